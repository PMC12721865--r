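#' @keywords internal
"_PACKAGE"

# Typed condition helper. All package errors carry class
# "synsieve_<class>_error" so callers can branch on failure modes.
abort_synsieve <- function(message, class) {
  stop(structure(
    class = c(paste0("synsieve_", class, "_error"),
              "synsieve_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Structured run logging
#'
#' Emits one tab-separated line `LEVEL<tab>operation<tab>message` to stderr
#' and, when a log file is active (see [set_log_file()]), appends it there.
#'
#' @param level One of `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param op Short name of the operation emitting the line.
#' @param msg Free-text message.
#' @return Invisibly, the formatted line.
#' @export
log_line <- function(level, op, msg) {
  line <- paste(level, op, msg, sep = "\t")
  message(line)
  logfile <- getOption("synsieve.logfile")
  if (!is.null(logfile)) {
    cat(line, "\n", sep = "", file = logfile, append = TRUE)
  }
  invisible(line)
}

#' Activate or deactivate the run log file
#'
#' @param path Path to append log lines to, or `NULL` to disable.
#' @return Invisibly, the previous setting.
#' @export
set_log_file <- function(path) {
  old <- getOption("synsieve.logfile")
  options(synsieve.logfile = path)
  invisible(old)
}

# Single scalar character, non-NA.
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Single finite number.
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
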