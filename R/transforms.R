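#' Sample skewness (third standardized moment)
#' @param x numeric vector.
#' @return `m3 / m2^1.5` with population moments; `NaN` for constant input.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) return(NaN)
  mean((x - mu)^3) / m2^1.5
}

.apply_transform <- function(x, transform, pre_scale = 1) {
  z <- x * pre_scale
  switch(transform,
         identity = z,
         log = log(z),
         sqrt = sqrt(z),
         cbrt = sign(z) * abs(z)^(1 / 3),
         cube = z^3,
         stop("unknown transform: ", transform))
}

#' Apply a transform specification to a value vector
#' @param x numeric vector.
#' @param spec a `transform_spec` from [choose_transform()], or a transform
#'   name.
#' @param pre_scale multiplier applied before the transform when `spec` is a
#'   plain name.
#' @return Transformed vector.
#' @export
apply_transform <- function(x, spec, pre_scale = 1) {
  if (inherits(spec, "transform_spec"))
    .apply_transform(x, spec$transform, spec$pre_scale)
  else .apply_transform(x, spec, pre_scale)
}

#' Choose a skewness-minimizing distribution-compressing transform
#'
#' Mirrors the feature pre-processing convention for right-skewed radiomics
#' features: candidate transforms are the identity, log, square root and
#' cube root; when the sample contains negative values only cubing is
#' admissible (it preserves sign and order).  Features bounded in (0, 1]
#' (e.g. histogram uniformity) are pre-multiplied by 1000 before the log so
#' the transformed scale matches the conventional `log(x * 1000)` form.
#' Among admissible candidates the one minimizing the absolute sample
#' skewness is returned; ties break in the order listed above.
#'
#' @param values numeric sample of the feature (>= 3 finite values).
#' @param feature_name optional name carried into the result.
#' @return Object of class `transform_spec`: `feature_name`, `transform`,
#'   `pre_scale`, `skewness` (after transform).
#' @export
choose_transform <- function(values, feature_name = NULL) {
  x <- values[is.finite(values)]
  if (length(x) < 3L) stop("need at least 3 finite values")
  mk <- function(tr, ps, sk)
    structure(list(feature_name = feature_name, transform = tr,
                   pre_scale = ps, skewness = sk), class = "transform_spec")
  if (stats::var(x) == 0) {
    warning("constant feature: identity transform")
    return(mk("identity", 1, NaN))
  }
  if (any(x < 0)) {
    return(mk("cube", 1, sample_skewness(.apply_transform(x, "cube"))))
  }
  pre <- if (max(x) <= 1 && min(x) > 0) 1000 else 1
  cand <- list(
    list(tr = "identity", ps = 1),
    if (min(x * pre) > 0) list(tr = "log", ps = pre),
    list(tr = "sqrt", ps = 1),
    list(tr = "cbrt", ps = 1))
  cand <- Filter(Negate(is.null), cand)
  sk <- vapply(cand, function(cc)
    abs(sample_skewness(.apply_transform(x, cc$tr, cc$ps))), numeric(1))
  best <- cand[[which.min(sk)]]   # which.min takes the first on ties
  mk(best$tr, best$ps,
     sample_skewness(.apply_transform(x, best$tr, best$ps)))
}

#' Build the transformed-plus-original candidate feature pool
#'
#' For each feature column, selects a transform with [choose_transform()]
#' and, when the transform is not the identity, appends the transformed
#' variant as an extra column named `<transform>_<feature>` — keeping both
#' the original and the transformed features in the candidate pool.
#'
#' @param features data frame of numeric feature columns.
#' @return List with `pool` (augmented data frame) and `specs` (named list
#'   of `transform_spec`s for the transformed variants).
#' @export
transform_pool <- function(features) {
  specs <- list()
  pool <- features
  for (nm in names(features)) {
    sp <- tryCatch(choose_transform(features[[nm]], nm),
                   warning = function(w) NULL, error = function(e) NULL)
    if (is.null(sp) || sp$transform == "identity") next
    newnm <- paste0(sp$transform, "_", nm)
    pool[[newnm]] <- apply_transform(features[[nm]], sp)
    specs[[newnm]] <- sp
  }
  list(pool = pool, specs = specs)
}
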