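#' Encode an aligned pair as hom/het/missing observations
#'
#' Haploid mode (two sequences): sites where both nucleotides are plain
#' A/C/G/T are coded 0 when equal and 1 when different; any gap, N or other
#' ambiguity makes the site missing (2).  Diploid mode (one sequence with
#' IUPAC codes): A/C/G/T are homozygous, the two-base ambiguity codes
#' R/Y/S/W/K/M are heterozygous, everything else (N, gaps, three-base
#' codes) is missing.
#'
#' @param a character string, character vector of single letters, or
#'   `Biostrings::DNAStringSet`-like object for the first haplotype (or the
#'   diploid consensus).
#' @param b second haplotype (omit for diploid mode).
#' @return integer vector of codes in {0, 1, 2}.
#' @examples
#' encode_observations("ACGT", "ACTT")  # 0 0 1 0
#' encode_observations("ARGT")          # 0 1 0 0
#' @export
encode_observations <- function(a, b = NULL) {
  to_chars <- function(x) {
    if (length(x) == 1L && is.character(x)) x <- strsplit(x, "")[[1]]
    toupper(as.character(x))
  }
  a <- to_chars(a)
  acgt <- c("A", "C", "G", "T")
  if (is.null(b)) {
    het <- c("R", "Y", "S", "W", "K", "M")
    out <- rep(2L, length(a))
    out[a %in% acgt] <- 0L
    out[a %in% het] <- 1L
    return(out)
  }
  b <- to_chars(b)
  if (length(a) != length(b))
    stop("sequence length mismatch: ", length(a), " vs ", length(b))
  ok <- a %in% acgt & b %in% acgt
  out <- rep(2L, length(a))
  out[ok & a == b] <- 0L
  out[ok & a != b] <- 1L
  out
}

#' Read an aligned FASTA pair into an observed sequence
#'
#' Contigs are matched positionally between the two files (or taken as the
#' two records of a single file); each contig pair must have equal length.
#' With a single record (or `diploid = TRUE`) sequences are interpreted as
#' unphased diploid consensus with IUPAC heterozygote codes.
#'
#' @param file_a FASTA file with one sequence per contig.
#' @param file_b second FASTA file (omit for a two-record single file or
#'   diploid input).
#' @param diploid force diploid interpretation of `file_a`.
#' @param max_missing_warn warn when the missing fraction exceeds this
#'   (default 0.15, above which joint fitting becomes unreliable).
#' @return an [rm_obs][observed_sequence].
#' @export
read_sample_pair <- function(file_a, file_b = NULL, diploid = FALSE,
                             max_missing_warn = 0.15) {
  sa <- Biostrings::readBStringSet(file_a)
  if (diploid) {
    codes_by_contig <- lapply(seq_along(sa), function(i)
      encode_observations(as.character(sa[[i]])))
    nm <- names(sa)
  } else {
    if (is.null(file_b)) {
      if (length(sa) != 2)
        stop("single-file haploid input must contain exactly 2 sequences")
      sb <- sa[2]; sa <- sa[1]
    } else sb <- Biostrings::readBStringSet(file_b)
    if (length(sa) != length(sb))
      stop("files contain different numbers of contigs")
    codes_by_contig <- lapply(seq_along(sa), function(i) {
      ca <- as.character(sa[[i]]); cb <- as.character(sb[[i]])
      if (nchar(ca) != nchar(cb))
        stop("length mismatch in contig ", names(sa)[i])
      encode_observations(ca, cb)
    })
    nm <- names(sa)
  }
  lens <- vapply(codes_by_contig, length, integer(1))
  ends <- cumsum(lens)
  obs <- observed_sequence(unlist(codes_by_contig),
                           contigs = cbind(c(0L, ends[-length(ends)]), ends),
                           contig_names = nm)
  mf <- mean(obs$codes == 2L)
  if (mf > max_missing_warn)
    warning(sprintf("%.1f%% missing data (recommended < %.0f%%): joint fitting may be unreliable; consider the fixed-prior decoding protocol",
                    100 * mf, 100 * max_missing_warn))
  obs
}

#' Read a pairwise sample from ms-style simulator output
#'
#' Minimal extraction of `segsites`/`positions` plus two haplotype rows;
#' positions are scaled to [0, 1) and mapped onto `L` discrete sites.
#' Sites where the two haplotypes differ are heterozygous, all others
#' homozygous.
#'
#' @param file path to ms-style output containing one replicate.
#' @param L sequence length in bases.
#' @return an `rm_obs`.
#' @export
read_ms_pair <- function(file, L) {
  lines <- readLines(file)
  pi <- grep("^positions:", lines)
  if (!length(pi)) stop("no 'positions:' line found")
  pos <- as.numeric(strsplit(sub("^positions:\\s*", "", lines[pi[1]]), "\\s+")[[1]])
  haps <- lines[(pi[1] + 1):length(lines)]
  haps <- haps[grepl("^[01]+$", haps)]
  if (length(haps) < 2) stop("need two haplotype rows")
  h1 <- as.integer(strsplit(haps[1], "")[[1]])
  h2 <- as.integer(strsplit(haps[2], "")[[1]])
  codes <- integer(L)
  site <- pmin(floor(pos * L) + 1L, L)
  codes[site[h1 != h2]] <- 1L
  observed_sequence(codes)
}

#' Write / read binned maps as BedGraph
#'
#' The first four columns (chrom, start, end, value; 0-based half-open) are
#' standard BedGraph; `missing_frac` and `n_sites` are appended so the
#' binned map round-trips.
#'
#' @param binned an `rm_binned`.
#' @param path output file.
#' @param contig_names optional names replacing numeric contig ids.
#' @export
write_bedgraph <- function(binned, path, contig_names = NULL) {
  stopifnot(inherits(binned, "rm_binned"))
  df <- as.data.frame(binned)
  if (!is.null(contig_names)) df$contig <- contig_names[df$contig]
  data.table::fwrite(df[, c("contig", "start", "end", "rho",
                            "missing_frac", "n_sites")],
                     path, sep = "\t", col.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_bedgraph
#' @param missing_threshold threshold used to re-derive the mask flag.
#' @export
read_bedgraph <- function(path, missing_threshold = 0.5) {
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "start", "end", "rho",
                                        "missing_frac", "n_sites"),
                          data.table = FALSE)
  if (is.character(df$contig)) df$contig <- match(df$contig, unique(df$contig))
  df$masked <- df$missing_frac > missing_threshold | is.na(df$rho)
  attr(df, "width") <- max(df$end - df$start)
  class(df) <- c("rm_binned", "data.frame")
  df
}

#' Write a per-site map as two-column text
#' @param map an `rm_map`.
#' @param path output file (position is 1-based; excluded sites are
#'   omitted).
#' @export
write_sitemap <- function(map, path) {
  stopifnot(inherits(map, "rm_map"))
  keep <- map$include
  data.table::fwrite(data.frame(position = which(keep), rho = map$rho[keep]),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Serialise a model fit as JSON (with a key=value header block)
#'
#' @param fit an `rm_fit`.
#' @param path output file; a plain key=value summary is written to
#'   `paste0(path, ".txt")` alongside the JSON.
#' @param seed optional seed to record.
#' @export
write_fit <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "rm_fit"))
  rec <- list(version = as.character(utils::packageVersion("rhomap")),
              t = fit$t, k = fit$k, theta = fit$theta,
              rho0 = fit$prior$rho0, alpha = fit$prior$alpha,
              delta = fit$prior$delta, loglik = fit$loglik,
              n_params = fit$n_params, aic = fit$aic,
              fit_demography = fit$fit_demography,
              knot_log_rates = if (!is.null(fit$demography$spline))
                fit$demography$spline$knot_log_rates else NULL,
              knot_times = if (!is.null(fit$demography$spline))
                fit$demography$spline$knot_times else NULL,
              converged = fit$convergence$converged,
              evaluations = fit$convergence$evaluations,
              seed = seed)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  kv <- vapply(rec[!vapply(rec, is.null, logical(1))], function(v)
    paste(format(v, digits = 12), collapse = ","), character(1))
  writeLines(paste0(names(kv), "=", kv), paste0(path, ".txt"))
  invisible(path)
}

#' @rdname write_fit
#' @param obs the observed sequence the fit refers to (used to rebuild the
#'   kernel and emissions).
#' @export
read_fit <- function(path, obs) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  demog <- if (!is.null(rec$knot_log_rates))
    spline_demography(rec$knot_log_rates, rec$knot_times)
  else constant_demography()
  mod <- assemble_model(rec$t, rec$k, rec$rho0, rec$alpha, rec$delta,
                        rec$theta, demog)
  structure(list(prior = mod$prior, demography = demog, theta = rec$theta,
                 t = rec$t, k = rec$k, loglik = rec$loglik,
                 n_params = rec$n_params, aic = rec$aic,
                 convergence = list(iterations = NA_integer_,
                                    evaluations = rec$evaluations,
                                    converged = rec$converged),
                 disc = mod$disc, kernel = mod$kernel,
                 emissions = mod$emissions,
                 fit_demography = isTRUE(rec$fit_demography),
                 data_hash = hash_obs(obs)),
            class = "rm_fit")
}

#' Write a dendrogram (with support values) as Newick
#' @param cluster result of [map_distance_cluster()].
#' @param path output file.
#' @param collapsed write the support-collapsed topology instead.
#' @export
write_newick <- function(cluster, path, collapsed = FALSE) {
  tr <- if (collapsed) cluster$collapsed else cluster$tree
  ape::write.tree(tr, file = path)
  invisible(path)
}
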