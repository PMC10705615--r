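# shared internal helpers

# round half away from zero at integer precision; scores are >= 0 here so
# this is half-up (base round() rounds half to even, which would put 19.5
# in the band below)
round_half_up <- function(x) {
  floor(x + 0.5)
}

# coerce an answer value to logical; accepts TRUE/FALSE, "yes"/"no", "y"/"n"
as_yes_no <- function(x, what = "answer") {
  if (is.logical(x) && length(x) == 1L && !is.na(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    v <- tolower(trimws(x))
    if (v %in% c("yes", "y", "true")) return(TRUE)
    if (v %in% c("no", "n", "false")) return(FALSE)
  }
  stop(what, " must be yes/no, got: ", deparse(x), call. = FALSE)
}

# fixed-format score printing: integers without decimals, otherwise one
# decimal place (Table-style "7.5")
format_score <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9,
         formatC(round(x), format = "d"),
         formatC(x, format = "f", digits = 1))
}

# validation report container -------------------------------------------

validation_report <- function(errors = character(), warnings = character()) {
  structure(list(errors = as.character(errors),
                 warnings = as.character(warnings)),
            class = "welfare_validation")
}

merge_reports <- function(...) {
  reps <- list(...)
  validation_report(
    errors = unlist(lapply(reps, `[[`, "errors"), use.names = FALSE),
    warnings = unlist(lapply(reps, `[[`, "warnings"), use.names = FALSE)
  )
}

#' @export
print.welfare_validation <- function(x, ...) {
  if (length(x$errors) == 0 && length(x$warnings) == 0) {
    cat("OK: no errors, no warnings\n")
  } else {
    if (length(x$errors)) cat(paste0("error: ", x$errors, "\n"), sep = "")
    if (length(x$warnings)) cat(paste0("warning: ", x$warnings, "\n"), sep = "")
  }
  invisible(x)
}

# TRUE iff the report carries no errors (warnings allowed)
is_valid <- function(report) length(report$errors) == 0L

stop_on_invalid <- function(report, what) {
  if (!is_valid(report)) {
    stop("invalid ", what, ": ", paste(report$errors, collapse = "; "),
         call. = FALSE)
  }
  invisible(TRUE)
}
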