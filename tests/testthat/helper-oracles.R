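# Independent brute-force oracles and small fixture builders.

# random integer-valued stack, dims (nz, ny, nx, nc)
random_stack <- function(nz = 10, ny = 8, nx = 8, nc = 3, max_int = 500,
                         roles = c(glia = 1, nsc = 2, neuron = 3)[seq_len(nc)]) {
  v <- array(as.double(sample(0:max_int, nz * ny * nx * nc, replace = TRUE)),
             dim = c(nz, ny, nx, nc))
  image_stack(v, roles)
}

# stack whose per-slice mean curves are prescribed per channel: every pixel
# of slice z in channel c holds curve[[c]][z]
curve_stack <- function(curves, ny = 4, nx = 4,
                        roles = c(glia = 1, nsc = 2, neuron = 3)) {
  nz <- length(curves[[1]])
  v <- array(0, dim = c(nz, ny, nx, length(curves)))
  for (ci in seq_along(curves))
    for (z in seq_len(nz))
      v[z, , , ci] <- curves[[ci]][z]
  image_stack(v, roles[seq_along(curves)])
}

# per-slice mean by explicit triple loop over ROI pixels
oracle_mean_by_depth <- function(stack, role, r) {
  v <- channel(stack, role)
  nz <- dim(v)[1]
  out <- numeric(nz)
  for (z in seq_len(nz)) {
    acc <- 0; npix <- 0
    for (y in (r$y0 + 1):r$y1) {
      for (x in (r$x0 + 1):r$x1) {
        acc <- acc + v[z, y, x]
        npix <- npix + 1
      }
    }
    out[z] <- acc / npix
  }
  out
}

# supra-threshold sum / count by explicit masking
oracle_masked_sum <- function(vol, thr) sum(vol[vol >= thr])
oracle_masked_count <- function(vol, thr) sum(vol >= thr)

# 26-connected component count via igraph on the voxel adjacency graph
oracle_component_count <- function(mask, min_volume = 1L) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  d <- dim(mask)
  ijk <- arrayInd(idx, d)
  pos <- setNames(seq_along(idx), idx)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- list()
  for (o in seq_len(nrow(offs))) {
    nb <- ijk + matrix(offs[o, ], nrow(ijk), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    hit <- lin %in% idx
    if (!any(hit)) next
    from <- pos[as.character(idx[which(ok)[hit]])]
    to <- pos[as.character(lin[hit])]
    edges[[length(edges) + 1L]] <- cbind(from, to)
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  sum(comp$csize >= min_volume)
}

# pooled two-sample t by the hand formula
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  s2p <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  tstat <- (mean(a) - mean(b)) / sqrt(s2p * (1 / na + 1 / nb))
  list(t = tstat, df = df, p_value = 2 * pt(-abs(tstat), df))
}

# dense-grid argmax of a parabolic interpolation oracle: least-squares
# quadratic through three points, vertex from the fitted coefficients
oracle_quadfit_vertex <- function(z, y) {
  fit <- lm(y ~ z + I(z^2))
  b <- coef(fit)
  -b[["z"]] / (2 * b[["I(z^2)"]])
}

# dense-grid argmax of a continuous profile
oracle_dense_argmax <- function(f, lo, hi, n = 1000L) {
  zs <- seq(lo, hi, length.out = n)
  zs[which.max(f(zs))]
}

# standard fed/starved analysis thresholds used across tests: one policy
# per role, held fixed across the conditions being compared
test_policies <- function() {
  list(glia = threshold_policy("glia", "absolute", 40),
       nsc = threshold_policy("nsc", "absolute", 90),
       neuron = threshold_policy("neuron", "absolute", 90))
}

cohort_metrics <- function(scenes, min_volume = 10L) {
  do.call(rbind, lapply(scenes, function(sc)
    niche_metrics(sc$stack, policies = test_policies(),
                  min_volume = min_volume)))
}
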