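#' Generate a synthetic HU voxel patch with requested feature tendencies
#'
#' Builds an ellipsoidal lesion mask inside an array of the given shape and
#' fills the in-mask voxels with HU values whose extracted first-order
#' features move in the requested direction.  Exact attainment of feature
#' values is not promised; monotone response is: a larger `sd` (or
#' `uniformity = "low"`) spreads the intensity histogram and lowers the
#' extracted uniformity, a negative `p2_5_shift` pulls the 2.5th percentile
#' down, `sd = 0` yields a constant patch (uniformity 1, entropy 0).
#'
#' @param target_features list with any of: `mean` (HU, default 40), `sd`
#'   (HU, default 20), `uniformity` (`"low"`/`"high"`), `p2_5_shift` (HU
#'   shift applied to the dark tail, e.g. -30).
#' @param shape integer length-3 array dimensions (slice, row, column).
#' @param spacing voxel spacing in mm.
#' @param seed RNG seed.
#' @return A [voxel_patch()] with out-of-mask voxels at -1000 HU (air).
#' @export
generate_patch <- function(target_features = list(), shape = c(8, 24, 24),
                           spacing = c(2.5, 0.7, 0.7), seed = 1) {
  if (any(shape < 1)) stop("`shape` must be positive")
  known <- c("mean", "sd", "uniformity", "p2_5_shift")
  extra <- setdiff(names(target_features), known)
  if (length(extra))
    stop("unsupported target feature(s): ", paste(extra, collapse = ", "))
  mu <- target_features$mean %||% 40
  sd <- target_features$sd %||% 20
  unif <- target_features$uniformity
  shift <- target_features$p2_5_shift %||% 0
  if (sd < 0) stop("`sd` must be >= 0")
  if (!is.null(unif)) {
    unif <- match.arg(unif, c("low", "high"))
    if (sd == 0 && unif == "low")
      stop("constraint error: sd = 0 is incompatible with low uniformity")
  }
  with_preserved_seed(seed, {
    ctr <- (shape + 1) / 2
    ax <- pmax(shape / 2 - 0.5, 0.5)
    g <- expand.grid(s = seq_len(shape[1]), r = seq_len(shape[2]),
                     c = seq_len(shape[3]))
    inside <- ((g$s - ctr[1]) / ax[1])^2 + ((g$r - ctr[2]) / ax[2])^2 +
      ((g$c - ctr[3]) / ax[3])^2 <= 1
    mask <- array(FALSE, dim = shape)
    mask[cbind(g$s, g$r, g$c)] <- inside
    n <- sum(mask)
    v <- if (sd == 0) rep(mu, n) else stats::rnorm(n, mu, sd)
    if (!is.null(unif)) {
      if (unif == "low" && sd > 0) {
        # bimodal spread widens the histogram support
        v <- v + sample(c(-3, 3) * max(sd, 10), n, replace = TRUE)
      } else if (unif == "high" && sd > 0) {
        v <- mu + round((v - mu) / (3 * sd)) * (3 * sd)  # quantize to 3 levels
      }
    }
    if (shift != 0) {
      k <- max(1L, ceiling(0.05 * n))
      tail_idx <- order(v)[seq_len(k)]
      v[tail_idx] <- v[tail_idx] + shift
    }
    intens <- array(-1000, dim = shape)
    intens[mask] <- v
    voxel_patch(intens, mask, spacing)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
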