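# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

tt_stop <- function(fmt, ..., class = "transtat_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "transtat_error", "error"),
                      call = sys.call(-1)))
}

tt_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a temporary, fully specified RNG state
#'
#' Seeds the Mersenne-Twister generator (inversion normals, rejection
#' sampling) so results are reproducible across R versions, then restores
#' whatever RNG state the caller had.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

# log10(x + 1), the display/analysis transform used throughout
log10p1 <- function(x) log10(x + 1)

# quantile with linear interpolation between order statistics (type 7),
# pinned here so normalization results are bit-reproducible
quantile_linear <- function(x, p) unname(stats::quantile(x, probs = p, type = 7, names = FALSE))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
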