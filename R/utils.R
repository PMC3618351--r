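#' @keywords internal
"_PACKAGE"

# Signal a classed error so callers/tests can distinguish format problems
# (bad input files) from usage problems (bad arguments).
xo_abort <- function(msg, class = "xomap_error", ...) {
  stop(errorCondition(msg, ..., class = c(class, "xomap_error", "error")))
}

xo_abort_format <- function(msg, ...) {
  xo_abort(msg, class = "xomap_format_error", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Offspring group codes
#'
#' The four backcross analysis groups: offspring of a female wild-type F1
#' (`FWT`), female knockout F1 (`FKO`), male wild-type F1 (`MWT`) and male
#' knockout F1 (`MKO`).  The first letter encodes the sex of the F1 parent
#' whose meiosis is observed.
#'
#' @return Character vector of the four group codes.
#' @export
group_codes <- function() c("FWT", "FKO", "MWT", "MKO")

# Sex of the recombining F1 parent for each group.
group_sex <- function(group) {
  ifelse(substr(group, 1, 1) == "F", "female", "male")
}

stopifnot_scalar_prob <- function(x, name, allow_zero = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x <= 1 && (x > 0 || (allow_zero && x == 0))
  if (!ok) xo_abort(sprintf("`%s` must be a single probability in %s",
                            name, if (allow_zero) "[0, 1]" else "(0, 1]"))
  invisible(x)
}
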