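#' @title Body-bar pebble-game rigidity analysis
#' @description Each atom is a 6-degree-of-freedom body; constraints are bars
#'   between bodies (5 bars for a rotatable covalent bond or a hydrogen bond,
#'   6 for a locked bond, 2 for a hydrophobic tether). The (6,6) pebble game
#'   matches degrees of freedom against bars, yielding the number of floppy
#'   modes (internal degrees of freedom plus the 6 rigid-body motions) and
#'   the decomposition into maximal rigid clusters.
#' @name rigidity
NULL

BAR_MULTIPLICITY <- c(covalent_single = 5L, covalent_locked = 6L,
                      hbond = 5L, tether = 2L)

# Directed pebble-shift search: find a free pebble reachable from `starts`
# along directed edges in D (integer count matrix), excluding `blocked`
# vertices from donating. On success, reverse the path and return TRUE.
shift_pebble <- function(env, starts, blocked) {
  n <- env$n
  visited <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)
  stack <- starts
  visited[starts] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(env$D[v, ] > 0L & !visited)
    for (w in nb) {
      visited[w] <- TRUE
      parent[w] <- v
      if (env$pebbles[w] > 0L && !(w %in% blocked)) {
        # reverse path w <- ... <- start; pebble moves to the path start
        env$pebbles[w] <- env$pebbles[w] - 1L
        u <- w
        while (!is.na(parent[u])) {
          p <- parent[u]
          env$D[p, u] <- env$D[p, u] - 1L
          env$D[u, p] <- env$D[u, p] + 1L
          u <- p
        }
        env$pebbles[u] <- env$pebbles[u] + 1L
        return(TRUE)
      }
      stack <- c(stack, w)
    }
  }
  FALSE
}

# gather up to `target` pebbles onto {u, v}; returns achieved count
gather_pebbles <- function(env, u, v, target) {
  repeat {
    have <- env$pebbles[u] + env$pebbles[v]
    if (have >= target) return(have)
    if (!shift_pebble(env, c(u, v), blocked = c(u, v))) return(have)
  }
}

#' Run the (6,6) body-bar pebble game
#'
#' @param network a `constraint_network` (apply the energy cutoff first).
#' @return Object of class `rigid_decomposition`: `cluster_of` (atom index ->
#'   cluster id, clusters numbered by decreasing size, ties by smallest
#'   member serial), `cluster_sizes`, `floppy_modes` (total unmatched
#'   pebbles, including the 6 rigid-body motions of a connected molecule),
#'   `n_redundant` (rejected bars), and `rotatable_dihedrals` (row indices
#'   into `network$edges` of covalent_single bonds not interior to a rigid
#'   cluster).
#' @export
pebble_game <- function(network) {
  stopifnot(inherits(network, "constraint_network"))
  n <- as.integer(network$n_atoms)
  edges <- network$edges
  edges$i <- as.integer(edges$i)
  edges$j <- as.integer(edges$j)
  if (n == 0 || nrow(edges) == 0) stop("empty constraint network")
  if (any(edges$i < 1 | edges$i > n | edges$j < 1 | edges$j > n)) {
    stop("edge endpoint outside atom set")
  }
  mult <- BAR_MULTIPLICITY[edges$kind]
  if (any(is.na(mult) | mult < 0)) stop("unknown edge kind or negative bar multiplicity")
  env <- new.env()
  env$n <- n
  env$pebbles <- rep(6L, n)
  env$D <- matrix(0L, n, n)
  accepted <- 0L
  redundant <- 0L
  for (k in seq_len(nrow(edges))) {
    u <- edges$i[k]; v <- edges$j[k]
    for (b in seq_len(mult[k])) {
      if (gather_pebbles(env, u, v, 7L) >= 7L) {
        env$pebbles[u] <- env$pebbles[u] - 1L
        env$D[u, v] <- env$D[u, v] + 1L
        accepted <- accepted + 1L
      } else {
        redundant <- redundant + 1L
      }
    }
  }
  floppy <- 6L * n - accepted
  # rigid-pair test: u,v are in a common rigid cluster iff at most 6 pebbles
  # can be gathered onto the pair (a 7th bar would be redundant)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  pair_rigid <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    u <- edges$i[k]; v <- edges$j[k]
    if (find(u) == find(v)) { pair_rigid[k] <- TRUE; next }
    if (gather_pebbles(env, u, v, 7L) < 7L) {
      pair_rigid[k] <- TRUE
      union_(u, v)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  serial <- network$structure$atoms$serial
  groups <- split(seq_len(n), roots)
  sizes <- vapply(groups, length, integer(1))
  min_serial <- vapply(groups, function(g) min(serial[g]), numeric(1))
  ord <- order(-sizes, min_serial)
  cluster_of <- integer(n)
  for (r in seq_along(ord)) cluster_of[groups[[ord[r]]]] <- r
  cluster_sizes <- sizes[ord]
  names(cluster_sizes) <- seq_along(ord)
  rot <- which(edges$kind == "covalent_single" & !pair_rigid)
  structure(list(cluster_of = cluster_of, cluster_sizes = cluster_sizes,
                 floppy_modes = floppy, n_redundant = redundant,
                 rotatable_dihedrals = rot, network = network),
            class = "rigid_decomposition")
}

#' @export
print.rigid_decomposition <- function(x, ...) {
  cat(sprintf(
    "<rigid_decomposition: %d clusters (largest %d of %d atoms), %d floppy modes, %d rotatable dihedrals>\n",
    length(x$cluster_sizes), x$cluster_sizes[1], length(x$cluster_of),
    x$floppy_modes, length(x$rotatable_dihedrals)))
  invisible(x)
}

#' Rigidity summary across energy cutoffs
#'
#' One pebble-game decomposition per cutoff. Lowering the cutoff (more
#' negative) removes hydrogen bonds, so the floppy-mode count is
#' non-decreasing and the largest-cluster fraction non-increasing along a
#' descending cutoff list.
#'
#' @param structure a protein `tcr_structure`.
#' @param params [network_params()].
#' @param e_cut_values numeric vector of cutoffs (all <= 0).
#' @return Data frame `(e_cut, n_hbonds, floppy_modes, n_clusters,
#'   largest_cluster_fraction)` with the decompositions in the
#'   `"decompositions"` attribute.
#' @export
rigidity_profile <- function(structure, params = network_params(),
                             e_cut_values = c(-2, -3)) {
  if (any(e_cut_values > 0)) stop("e_cut values must be <= 0")
  base <- build_constraint_network(structure, params)
  rows <- list(); decs <- list()
  for (ec in e_cut_values) {
    net <- apply_energy_cutoff(base, ec)
    dec <- pebble_game(net)
    rows[[length(rows) + 1]] <- data.frame(
      e_cut = ec,
      n_hbonds = sum(net$edges$kind == "hbond"),
      floppy_modes = dec$floppy_modes,
      n_clusters = length(dec$cluster_sizes),
      largest_cluster_fraction = dec$cluster_sizes[1] / net$n_atoms
    )
    decs[[as.character(ec)]] <- dec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "decompositions") <- decs
  out
}

#' Write a rigid-cluster decomposition as TSV
#' @param decomposition a `rigid_decomposition`.
#' @param path output path.
#' @export
write_decomposition_tsv <- function(decomposition, path) {
  at <- decomposition$network$structure$atoms
  df <- data.frame(atom = paste0(at$chain_id, at$res_seq, ":", at$name),
                   serial = at$serial, cluster = decomposition$cluster_of)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a structure with cluster ids in the B-factor column
#'
#' Visualisation aid: colour by B-factor shows the rigid clusters.
#' @param decomposition a `rigid_decomposition`.
#' @param path output PDB path.
#' @export
write_cluster_pdb <- function(decomposition, path) {
  s <- decomposition$network$structure
  s$atoms$b_factor <- as.numeric(decomposition$cluster_of)
  write_pdb(s, path)
}
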