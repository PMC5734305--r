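# Independent oracles used to cross-check package computations. These are
# deliberately implemented by different routes than the package internals.

# Cylinder + phase helix fit by direct optimization: find the axis
# direction that makes all points equidistant from a best-fit line, then
# read rise and twist from the projections. Independent of the package's
# chord-difference/Kasa fitting.
oracle_helix_fit <- function(pts) {
  obj <- function(ang) {
    u <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    proj <- pts - (pts %*% u) %*% t(u)
    ctr <- colMeans(proj)
    r <- sqrt(rowSums(sweep(proj, 2, ctr)^2))
    stats::var(r)
  }
  best <- NULL
  for (start in list(c(0.01, 0), c(pi / 4, 1), c(pi / 2, 2), c(1, 4))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ang <- best$par
  u <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
  if (sum((pts[nrow(pts), ] - pts[1, ]) * u) < 0) u <- -u
  z <- as.vector(pts %*% u)
  proj <- pts - (pts %*% u) %*% t(u)
  ctr <- colMeans(proj)
  rel <- sweep(proj, 2, ctr)
  radius <- mean(sqrt(rowSums(rel^2)))
  ref <- rel[1, ] / sqrt(sum(rel[1, ]^2))
  ref2 <- pracma::cross(u, ref)
  phase <- atan2(rel %*% ref2, rel %*% ref)
  dph <- diff(phase)
  dph <- atan2(sin(dph), cos(dph))
  list(radius = radius, rise = mean(diff(z)),
       twist_deg = mean(dph) * 180 / pi,
       res_per_turn = 360 / abs(mean(dph) * 180 / pi))
}

# Brute-force knobs-into-holes reference: plain loops over residues, side
# chain centers computed by simple averaging.
oracle_kih <- function(model, cutoff = 7) {
  res <- unique(model[, c("chain", "res_num", "res_name")])
  centers <- matrix(NA_real_, nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    sub <- model[model$chain == res$chain[i] & model$res_num == res$res_num[i], ]
    sc <- sub[!(sub$atom %in% c("N", "CA", "C", "O")), ]
    if (nrow(sc) == 0) sc <- sub[sub$atom == "CA", ]
    centers[i, ] <- c(mean(sc$x), mean(sc$y), mean(sc$z))
  }
  knobs <- list()
  for (i in seq_len(nrow(res))) {
    rng <- range(res$res_num[res$chain == res$chain[i]])
    if (res$res_num[i] %in% rng) next
    for (ch in setdiff(unique(res$chain), res$chain[i])) {
      targets <- which(res$chain == ch)
      d <- sqrt(colSums((t(centers[targets, , drop = FALSE]) - centers[i, ])^2))
      if (sum(d <= cutoff) >= 4) {
        knobs[[length(knobs) + 1L]] <- data.frame(
          knob_chain = res$chain[i], knob_res = res$res_num[i],
          hole_chain = ch, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(knobs) == 0) {
    return(data.frame(knob_chain = character(), knob_res = integer(),
                      hole_chain = character()))
  }
  do.call(rbind, knobs)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         nrow = 3, byrow = TRUE)
}
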