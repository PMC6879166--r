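"""Structured-coalescent pair simulation via msprime.

Reads a JSON config, simulates haploid samples under a two-population
pulse-admixture demography or a three-population species tree, applies a
piecewise-constant recombination landscape, and writes, for each requested
sample pair, the positions (1-based) where the two haplotypes differ.

Time is in coalescent units (pairwise coalescence rate 1 within a
population): all population sizes are 0.5 diploids, so one generation is
one coalescent time unit, per-site recombination rate is rho/2 and
per-site mutation rate theta/2.

Config keys:
  L, seed, theta
  segments: [[start, end, rho], ...]        (0-based half-open, per-site rho)
  demography: {"type": "panmictic"}
              {"type": "introgression", "split": 2.0,
               "pulse_time": 0.125, "pulse_prop": 0.1}
              {"type": "three_pop", "t12": 0.3, "t123": 0.6}
  pairs: for introgression/panmictic: number of pairs (all from the target
         population); for three_pop: pairs per population
  out: output JSON path
"""

import json
import sys

import msprime


def build_demography(cfg):
    kind = cfg["type"]
    dem = msprime.Demography()
    if kind == "panmictic":
        dem.add_population(name="T", initial_size=0.5)
        return dem, [("T", None)]
    if kind == "introgression":
        dem.add_population(name="T", initial_size=0.5)
        dem.add_population(name="S", initial_size=0.5)
        dem.add_population(name="ANC", initial_size=0.5)
        dem.add_mass_migration(time=cfg["pulse_time"], source="T", dest="S",
                               proportion=cfg["pulse_prop"])
        dem.add_population_split(time=cfg["split"], derived=["T", "S"],
                                 ancestral="ANC")
        return dem, [("T", None)]
    if kind == "three_pop":
        for name in ["P1", "P2", "P3", "A12", "ANC"]:
            dem.add_population(name=name, initial_size=0.5)
        dem.add_population_split(time=cfg["t12"], derived=["P1", "P2"],
                                 ancestral="A12")
        dem.add_population_split(time=cfg["t123"], derived=["A12", "P3"],
                                 ancestral="ANC")
        return dem, [("P1", None), ("P2", None), ("P3", None)]
    raise ValueError("unknown demography type: " + kind)


def main(path):
    with open(path) as fh:
        cfg = json.load(fh)
    L = int(cfg["L"])
    seed = int(cfg["seed"])
    segs = cfg["segments"]
    pos = [int(s[0]) for s in segs] + [L]
    rate = [float(s[2]) / 2.0 for s in segs]  # rho -> per-generation rate
    rate_map = msprime.RateMap(position=pos, rate=rate)

    dem, sampled_pops = build_demography(cfg["demography"])
    npairs = int(cfg["pairs"])
    samples = [msprime.SampleSet(2 * npairs, population=p, ploidy=1)
               for p, _ in sampled_pops]

    ts = msprime.sim_ancestry(samples=samples, demography=dem,
                              sequence_length=L,
                              recombination_rate=rate_map,
                              discrete_genome=True, random_seed=seed)
    ts = msprime.sim_mutations(ts, rate=float(cfg["theta"]) / 2.0,
                               random_seed=seed + 1,
                               model=msprime.BinaryMutationModel())

    # pair up consecutive samples within each population
    out_pairs = {}
    node_pop = {}
    for s in ts.samples():
        node_pop.setdefault(ts.node(s).population, []).append(s)
    pair_list = []
    names = []
    for pi, (pname, _) in enumerate(sampled_pops):
        pid = [p.id for p in dem.populations if p.name == pname][0]
        nodes = node_pop[pid]
        for j in range(npairs):
            pair_list.append((nodes[2 * j], nodes[2 * j + 1]))
            names.append(f"{pname}_pair{j + 1}")
    het = {nm: [] for nm in names}
    sample_index = {s: i for i, s in enumerate(ts.samples())}
    for var in ts.variants():
        g = var.genotypes
        p = int(var.site.position) + 1  # 1-based site
        for nm, (a, b) in zip(names, pair_list):
            if g[sample_index[a]] != g[sample_index[b]]:
                het[nm].append(p)
    for nm in het:  # collapse multiple mutations at one site
        het[nm] = sorted(set(het[nm]))

    with open(cfg["out"], "w") as fh:
        json.dump({"L": L, "pairs": het}, fh)


if __name__ == "__main__":
    main(sys.argv[1])
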