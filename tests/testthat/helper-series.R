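# shared fixture builders

# short series on consecutive dates starting 2015-01-22
mk_series <- function(values, start = as.Date("2015-01-22")) {
  daily_series(start + seq_along(values) - 1L, values)
}

# temporary CSV from a data frame, cleaned up with the test
tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

guangzhou <- function() guangzhou_pm25()$forecasts
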