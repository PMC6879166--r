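#' Structured-coalescent pair simulation (external simulator)
#'
#' Pairwise sequential simulation with population structure is a different
#' machine from the panmictic SMC' simulator, so structured scenarios
#' (introgression pulses, multi-population cohorts sharing one landscape)
#' are generated with msprime, driven through the bundled Python script.
#' Requires a `python` with msprime on the PATH.
#'
#' Time is in coalescent units (pairwise coalescence rate 1); the
#' introgression design is: source/target split `split` units ago, a pulse
#' replacing `pulse_prop` of the target `pulse_time` units ago, sampling
#' from the target.
#'
#' @param landscape an `rm_landscape` of per-site rho.
#' @param theta scaled mutation rate (homogeneous).
#' @param demography_spec list, e.g. `list(type = "introgression", split =
#'   2.0, pulse_time = 0.125, pulse_prop = 0.1)` or `list(type =
#'   "three_pop", t12 = 0.3, t123 = 0.6)` or `list(type = "panmictic")`.
#' @param pairs number of sample pairs (per population for `three_pop`).
#' @param seed RNG seed passed to msprime.
#' @param python python interpreter to use.
#' @return named list of `rm_obs`, one per simulated pair.
#' @export
sim_structured_pairs <- function(landscape, theta, demography_spec,
                                 pairs = 1, seed = 1L, python = "python") {
  stopifnot(inherits(landscape, "rm_landscape"))
  if (Sys.which(python) == "")
    stop("no '", python, "' interpreter found on the PATH")
  script <- system.file("python", "structured_pair.py", package = "rhomap")
  if (script == "") stop("bundled python driver not found")
  cfg_file <- tempfile(fileext = ".json")
  out_file <- tempfile(fileext = ".json")
  on.exit(unlink(c(cfg_file, out_file)), add = TRUE)
  segs <- landscape$segments
  cfg <- list(L = landscape$L, seed = as.integer(seed), theta = theta,
              segments = lapply(seq_len(nrow(segs)), function(i)
                c(segs$start[i], segs$end[i], landscape$base * segs$scale[i])),
              demography = demography_spec, pairs = as.integer(pairs),
              out = out_file)
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  status <- system2(python, c(script, cfg_file), stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_file))
    stop("msprime driver failed:\n", paste(status, collapse = "\n"))
  res <- jsonlite::read_json(out_file, simplifyVector = TRUE)
  lapply(res$pairs, function(p) {
    codes <- integer(res$L)
    if (length(p)) codes[unlist(p)] <- 1L
    observed_sequence(codes)
  })
}
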