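#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The class labels used throughout the package
#'
#' Apnea is the positive class and always comes first; all factors, score
#' matrices and confusion counts follow this ordering.
#'
#' @return Character vector `c("apnea", "normal")`.
#' @export
apnea_classes <- function() c("apnea", "normal")

# Coerce labels (factor / "A","N" / "apnea","normal") to the canonical factor.
as_apnea_factor <- function(labels) {
  x <- as.character(labels)
  x[x == "A"] <- "apnea"
  x[x == "N"] <- "normal"
  bad <- setdiff(unique(x), apnea_classes())
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected 'apnea'/'A' or 'normal'/'N')")
  }
  factor(x, levels = apnea_classes())
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name,
                 format(lower), format(upper)))
  }
  invisible(x)
}
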