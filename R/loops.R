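#' @title CDR loop amplitude analysis
#' @description Aligns generated variants on the stable base of each chain
#'   (the non-loop residues of the N-terminal domain, residues 6-110) and
#'   measures the maximal amplitude of each loop's apex across the variant
#'   set, producing the per-loop / per-structure summary table.
#' @name loop_analysis
NULL

#' Stable-base residue set for a chain
#'
#' The stable base is the N-terminal-domain interval (default 6-110) minus
#' the loop intervals on that chain.
#'
#' @param loops loop-definition data frame.
#' @param chain_id chain identifier.
#' @param domain_range inclusive interval, default `c(6, 110)`.
#' @return Integer vector of residue numbers.
#' @export
stable_base <- function(loops, chain_id, domain_range = c(6, 110)) {
  base <- seq(domain_range[1], domain_range[2])
  lp <- loops[loops$chain_id == chain_id, , drop = FALSE]
  for (i in seq_len(nrow(lp))) {
    base <- setdiff(base, seq(lp$start[i], lp$end[i]))
  }
  if (length(base) == 0) stop("stable base empty for chain ", chain_id)
  base
}

#' Align conformers onto a reference on the stable base
#'
#' Each conformer is superposed onto the reference using the CA atoms of the
#' base residues only; each chain is aligned independently (the interdomain
#' linker acts as a flexible joint, so a global fit would mix domain motion
#' into the loop measurements).
#'
#' @param variants list of coordinate matrices (atom-table order of
#'   `reference`) or variant objects with a `coords` element.
#' @param reference the reference `tcr_structure`.
#' @param chain_id chain to align.
#' @param base residue numbers of the stable base (see [stable_base()]).
#' @return List of aligned coordinate matrices (full atom set, transformed
#'   by the per-chain base fit).
#' @export
align_on_stable_base <- function(variants, reference, chain_id, base) {
  at <- reference$atoms
  base_idx <- which(at$chain_id == chain_id & at$name == "CA" &
                      at$res_seq %in% base)
  if (length(base_idx) < 3) stop("fewer than 3 base CA atoms in chain ", chain_id)
  ref_xyz <- coords_matrix(reference)
  lapply(variants, function(v) {
    X <- if (is.list(v) && !is.null(v$coords)) v$coords else as.matrix(v)
    if (nrow(X) != nrow(at)) stop("variant atom count mismatch")
    fit <- kabsch_superpose(X[base_idx, , drop = FALSE],
                            ref_xyz[base_idx, , drop = FALSE])
    apply_transform(fit, X)
  })
}

#' Apex amplitude of a loop over a conformer set
#'
#' The apex is the CA of the median residue of the loop range (lower median
#' for even-length loops). The amplitude is the maximum pairwise distance
#' between apex positions across the reference plus all variants
#' (`method = "max_pairwise"`, the default), or the maximum excursion from
#' the reference apex (`method = "max_excursion"`).
#'
#' @param aligned_variants list of aligned coordinate matrices (from
#'   [align_on_stable_base()]).
#' @param reference the reference `tcr_structure`.
#' @param loop one-row loop definition.
#' @param method amplitude definition (see above).
#' @return Amplitude in Angstrom with the apex residue number in the
#'   `"apex_res"` attribute.
#' @export
apex_amplitude <- function(aligned_variants, reference, loop,
                           method = c("max_pairwise", "max_excursion")) {
  method <- match.arg(method)
  at <- reference$atoms
  rng <- seq(loop$start, loop$end)
  present <- intersect(rng, at$res_seq[at$chain_id == loop$chain_id &
                                         at$name == "CA"])
  if (length(present) == 0) stop("no loop CA atoms for ", loop$loop_name)
  apex_res <- present[ceiling(length(present) / 2)]
  if (length(present) %% 2 == 0) apex_res <- present[length(present) / 2]
  apex_idx <- which(at$chain_id == loop$chain_id & at$res_seq == apex_res &
                      at$name == "CA")[1]
  pts <- rbind(coords_matrix(reference)[apex_idx, , drop = FALSE],
               do.call(rbind, lapply(aligned_variants, function(X) {
                 X[apex_idx, , drop = FALSE]
               })))
  if (nrow(pts) == 1) {
    amp <- 0
  } else if (method == "max_pairwise") {
    amp <- max(stats::dist(pts))
  } else {
    amp <- max(sqrt(rowSums((pts[-1, , drop = FALSE] -
                               matrix(pts[1, ], nrow(pts) - 1, 3, byrow = TRUE))^2)))
  }
  attr(amp, "apex_res") <- apex_res
  amp
}

#' Build an amplitude report
#'
#' @param amplitudes matrix or data frame of apex amplitudes: rows = loop
#'   names, columns = structures.
#' @return Object of class `amplitude_report`: the amplitude table plus
#'   `structure_means` (mean over each structure's loops) and `loop_means`
#'   (mean over structures per loop name), unrounded; `format()` renders the
#'   1-decimal display table.
#' @export
amplitude_report <- function(amplitudes) {
  A <- as.matrix(amplitudes)
  if (any(A < 0, na.rm = TRUE)) stop("amplitudes must be >= 0")
  if (any(is.na(A))) stop("missing loop amplitude in report input")
  structure(list(amplitudes = A,
                 structure_means = colMeans(A),
                 loop_means = rowMeans(A)),
            class = "amplitude_report")
}

#' @export
format.amplitude_report <- function(x, ...) {
  tab <- cbind(round(x$amplitudes, 1), mean = round(x$loop_means, 1))
  rbind(tab, mean = c(round(x$structure_means, 1), NA))
}

#' @export
print.amplitude_report <- function(x, ...) {
  print(format(x))
  invisible(x)
}

#' Write an amplitude report as TSV
#' @param report an `amplitude_report`.
#' @param path output path.
#' @param method label recording which amplitude definition produced the
#'   table.
#' @export
write_amplitude_report <- function(report, path, method = "max_pairwise") {
  tab <- format(report)
  df <- data.frame(loop = rownames(tab), tab, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# apex amplitude (A), method=", method), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Measure all loop amplitudes for a variant set
#'
#' Convenience wrapper: for each chain (and per-loop domain, when the loop
#' table carries `domain_start`/`domain_end` columns), aligns the variants
#' on the stable base, then measures every loop of that group.
#'
#' @param variants list of variants (coordinate matrices or objects with
#'   `coords`).
#' @param reference the reference `tcr_structure`.
#' @param loops loop-definition data frame; optional columns `domain_start`,
#'   `domain_end` override `domain_range` per loop (each loop is then
#'   aligned on its own domain's non-loop residues).
#' @param domain_range stable-base interval (default `c(6, 110)`).
#' @param method amplitude definition, see [apex_amplitude()].
#' @return Named numeric vector of amplitudes (one per loop).
#' @export
measure_loop_amplitudes <- function(variants, reference, loops,
                                    domain_range = c(6, 110),
                                    method = "max_pairwise") {
  validate_loops(loops, reference)
  if (!("domain_start" %in% names(loops))) {
    loops$domain_start <- domain_range[1]
    loops$domain_end <- domain_range[2]
  }
  out <- numeric(nrow(loops))
  names(out) <- loops$loop_name
  groups <- split(seq_len(nrow(loops)),
                  paste(loops$chain_id, loops$domain_start, loops$domain_end))
  for (idx in groups) {
    ch <- loops$chain_id[idx[1]]
    dr <- c(loops$domain_start[idx[1]], loops$domain_end[idx[1]])
    base <- stable_base(loops, ch, dr)
    aligned <- align_on_stable_base(variants, reference, ch, base)
    for (i in idx) {
      out[i] <- as.numeric(apex_amplitude(aligned, reference, loops[i, ],
                                          method = method))
    }
  }
  out
}
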