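## Timestamped log lines to standard error (and optionally a file).
## Verbosity: options(betadose.verbose = FALSE) silences; an optional sink
## file is set with options(betadose.log_file = path).
bd_log <- function(fmt, ...) {
  line <- sprintf("[betadose %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  if (isTRUE(getOption("betadose.verbose", TRUE))) message(line)
  logfile <- getOption("betadose.log_file", NULL)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}
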