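#' Topographic projection edge list
#'
#' Builds the radius-based fan-out of one projection: presynaptic cell `i`
#' (0-based) connects to every target `j` with
#' `|j - round(i * n_post / n_pre)| <= radius`, indices clipped at the array
#' bounds (no wraparound). Self-connections are excluded unless
#' `allow_self` (only meaningful when source and target are the same
#' population).
#'
#' @param n_pre,n_post Population sizes (>= 1).
#' @param radius Fan-out radius in target index units (>= 0).
#' @param allow_self Keep edges with `pre == post`?
#' @return A data.frame with 0-based integer columns `pre` and `post`.
#' @examples
#' build_projection(10, 10, radius = 1, allow_self = FALSE)
#' @export
build_projection <- function(n_pre, n_post, radius, allow_self = TRUE) {
  stopifnot(n_pre >= 1, n_post >= 1, radius >= 0)
  pre <- integer(0); post <- integer(0)
  for (i in seq_len(n_pre) - 1L) {
    ctr <- round(i * n_post / n_pre)
    j <- max(0L, ctr - radius):min(n_post - 1L, ctr + radius)
    if (!allow_self) j <- j[j != i]
    pre <- c(pre, rep.int(i, length(j)))
    post <- c(post, as.integer(j))
  }
  data.frame(pre = pre, post = post)
}

proj_endpoints <- list(
  py_py = c("py", "py"), py_inh = c("py", "inh"), inh_py = c("inh", "py"),
  py_tc = c("py", "tc"), py_re = c("py", "re"), tc_py = c("tc", "py"),
  tc_inh = c("tc", "inh"), tc_re = c("tc", "re"), re_tc = c("re", "tc"),
  re_re = c("re", "re"))

#' Build the full network
#'
#' Instantiates the four populations at their configured counts and all
#' topographic projections (PY->PY with depressing AMPA + NMDA, PY->INH,
#' INH->PY GABA-A, the corticothalamic and thalamocortical AMPA pathways,
#' RE->TC GABA-A + GABA-B and RE->RE GABA-A). Per-connection conductances
#' are the configured per-target totals divided by each target's actual
#' in-degree, so boundary cells receive comparable total drive. Projections
#' touching an empty population are skipped. Construction is deterministic:
#' no random numbers are drawn.
#'
#' @param cfg A config object.
#' @return A `somnotc_network`: population sizes, per-projection edge lists
#'   with per-edge weights (uS), and 1-D spatial coordinates (um) of every
#'   compartment for the LFP forward model.
#' @export
build_network <- function(cfg) {
  validate_config(cfg)
  n <- cfg$populations
  projections <- list()
  for (pj in names(proj_endpoints)) {
    ep <- proj_endpoints[[pj]]
    cn <- cfg$connectivity[[pj]]
    if (n[[ep[1]]] < 1 || n[[ep[2]]] < 1) next
    if (cn$g_ampa + cn$g_nmda + cn$g_gabaa + cn$g_gabab <= 0) next
    edges <- build_projection(n[[ep[1]]], n[[ep[2]]], cn$radius,
                              allow_self = isTRUE(cn$allow_self) ||
                                ep[1] != ep[2])
    if (nrow(edges) == 0) next
    indeg <- tabulate(edges$post + 1L, nbins = n[[ep[2]]])
    wfrac <- 1 / indeg[edges$post + 1L]
    projections[[pj]] <- list(
      name = pj, source = ep[1], target = ep[2], spec = cn,
      edges = edges,
      w_ampa = cn$g_ampa * wfrac, w_nmda = cn$g_nmda * wfrac,
      w_gabaa = cn$g_gabaa * wfrac, w_gabab = cn$g_gabab * wfrac)
  }
  structure(list(populations = n, projections = projections,
                 coords = network_coords(cfg), config = cfg),
            class = "somnotc_network")
}

# 1-D layout: each population spans the same cortical extent; cortical
# dendrites sit dend_offset_um above the somata, thalamus below the cortex.
network_coords <- function(cfg) {
  n <- cfg$populations
  pitch <- cfg$lfp$pitch_um
  span <- max(1L, n$py) * pitch
  layer <- function(m, y) {
    if (m < 1)
      return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
    cbind(x = (seq_len(m) - (m + 1) / 2) * (span / m), y = y, z = 0)
  }
  list(
    py_soma = layer(n$py, 0),
    py_dend = layer(n$py, cfg$lfp$dend_offset_um),
    inh_soma = layer(n$inh, 0),
    inh_dend = layer(n$inh, cfg$lfp$dend_offset_um),
    tc = layer(n$tc, -3000),
    re = layer(n$re, -2500))
}

#' Export a network's edge lists as plain text
#'
#' One edge per line: `projection source_index target_index receptor weight`,
#' tab-separated, indices 0-based. Useful for inspection and regression
#' comparisons.
#'
#' @param net A `somnotc_network`.
#' @param path Output file; `NULL` returns the data.frame instead.
#' @return The edge table (invisibly when written to a file).
#' @export
export_edges <- function(net, path = NULL) {
  rows <- list()
  for (pr in net$projections) {
    for (rec in c("ampa", "nmda", "gabaa", "gabab")) {
      w <- pr[[paste0("w_", rec)]]
      if (all(w <= 0)) next
      rows[[paste(pr$name, rec)]] <- data.frame(
        projection = pr$name, pre = pr$edges$pre, post = pr$edges$post,
        receptor = rec, weight = w)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(path)) return(out)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' @export
print.somnotc_network <- function(x, ...) {
  p <- x$populations
  cat("somnotc network: PY=", p$py, " INH=", p$inh, " TC=", p$tc,
      " RE=", p$re, "\n", sep = "")
  for (pr in x$projections)
    cat(sprintf("  %-7s %5d edges (radius %g)\n", pr$name,
                nrow(pr$edges), pr$spec$radius))
  invisible(x)
}
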