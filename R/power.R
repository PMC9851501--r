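# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Bootstrap power curve for the two-sample KS test
#'
#' Estimates, by resampling with replacement, how reliably the KS test
#' detects the difference between a target shift distribution and a control
#' shift distribution at matched sample sizes. For each size \code{n} on the
#' grid, \code{n_replicates} independent pairs of size-\code{n} samples are
#' drawn (one from each pool, independently) and the fraction of raw
#' two-sided KS p-values below each alpha level is recorded. No multiplicity
#' correction is applied inside the bootstrap. Draws are made size-major,
#' replicate-minor from a single seeded generator, so the curve is exactly
#' reproducible.
#'
#' @param target_shifts,control_shifts nonempty numeric pools resampled from.
#' @param sizes sample-size grid; default 50 to 235 in steps of 5.
#' @param n_replicates resamples per size; default 500.
#' @param alpha_levels significance levels; default 1\% and 5\%.
#' @param seed integer seed.
#' @return Object of class \code{bootstrap_power_curve}: list with
#'   \code{sizes}, \code{n_replicates}, \code{alpha_levels},
#'   \code{fraction_significant} (matrix, sizes x alphas), \code{seed}.
#' @export
bootstrap_power <- function(target_shifts, control_shifts,
                            sizes = seq(50, 235, by = 5),
                            n_replicates = 500,
                            alpha_levels = c(0.01, 0.05),
                            seed = 1L) {
  if (!length(target_shifts) || !length(control_shifts))
    stop("both resampling pools must be nonempty", call. = FALSE)
  if (any(sizes < 2)) stop("sizes must be at least 2", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be at least 1", call. = FALSE)
  frac <- matrix(NA_real_, length(sizes), length(alpha_levels),
                 dimnames = list(sizes, alpha_levels))
  with_seed(seed, {
    for (i in seq_along(sizes)) {
      n <- sizes[i]
      p <- vapply(seq_len(n_replicates), function(r) {
        a <- sample(target_shifts, n, replace = TRUE)
        b <- sample(control_shifts, n, replace = TRUE)
        ks_p(a, b)
      }, numeric(1))
      frac[i, ] <- vapply(alpha_levels, function(al) mean(p < al), numeric(1))
    }
  })
  structure(
    list(sizes = sizes, n_replicates = n_replicates,
         alpha_levels = alpha_levels, fraction_significant = frac,
         seed = seed),
    class = "bootstrap_power_curve"
  )
}

#' @export
print.bootstrap_power_curve <- function(x, ...) {
  cat(sprintf("Bootstrap KS power curve: %d sizes (%d..%d), %d replicates, seed %d\n",
              length(x$sizes), min(x$sizes), max(x$sizes), x$n_replicates,
              x$seed))
  df <- as.data.frame(x)
  show <- df[df$size %in% stats::quantile(x$sizes, c(0, .25, .5, .75, 1),
                                          type = 1), ]
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.bootstrap_power_curve <- function(x, ...) {
  grid <- expand.grid(size = x$sizes, alpha = x$alpha_levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid$n_replicates <- x$n_replicates
  grid$fraction_significant <- as.vector(x$fraction_significant)
  grid
}

#' @export
plot.bootstrap_power_curve <- function(x, ...) {
  graphics::matplot(x$sizes, x$fraction_significant, type = "b", pch = 19,
                    lty = 1, xlab = "sample size n",
                    ylab = "fraction of significant KS tests",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", bty = "n",
                   legend = paste("alpha =", x$alpha_levels),
                   col = seq_along(x$alpha_levels), lty = 1, pch = 19)
  invisible(x)
}
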