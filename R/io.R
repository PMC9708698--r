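# Tabular I/O: tab-delimited UTF-8 text with a header row and '.' decimals,
# numbers written with 17 significant digits so round trips are lossless.

format_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- format_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

read_tsv <- function(path) {
  # quote = "": fields like the sugar-proton name H4' contain apostrophes
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

#' Write transfer intensity series to a TSV table
#'
#' Columns: `residue`, `condition`, `delay_s`, `intensity`, `acq_order`,
#' `noise_sd`.
#'
#' @param series_list list of [intensity_series].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_intensity_table <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(residue = series_residue(s), condition = series_condition(s),
               delay_s = s$delay_s, intensity = s$intensity,
               acq_order = s$acq_order, noise_sd = series_noise_sd(s))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = character(), condition = character(),
               delay_s = numeric(), intensity = numeric(),
               acq_order = integer(), noise_sd = numeric())
  write_tsv(df, path)
  invisible(path)
}

#' Read a transfer intensity table
#'
#' @param path a TSV written by [write_intensity_table].
#' @return A list of [intensity_series], one per (residue, condition).
#' @export
read_intensity_table <- function(path) {
  df <- read_tsv(path)
  if (nrow(df) == 0) return(list())
  key <- interaction(df$residue, df$condition, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    intensity_series(g$delay_s, g$intensity, residue = g$residue[1],
                     condition = g$condition[1], noise_sd = g$noise_sd[1],
                     acq_order = g$acq_order)
  })
  names(out) <- vapply(out, function(s)
    paste(series_residue(s), series_condition(s), sep = "|"), "")
  out
}

#' Write relaxation-recovery series to a TSV table
#'
#' As [write_intensity_table] with an additional `kind` column
#' (`"inversion"` or `"saturation"`); the water series carry
#' `residue = "water"`.
#'
#' @param series_list list of [intensity_series]; the recovery kind is
#'   inferred from the residue label (`"water"` means saturation) unless a
#'   `kind` attribute is present.
#' @param path output file.
#' @export
write_recovery_table <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    kind <- attr(s, "kind")
    if (is.null(kind))
      kind <- if (identical(series_residue(s), "water")) "saturation" else
        "inversion"
    data.frame(kind = kind, residue = series_residue(s),
               condition = series_condition(s),
               delay_s = s$delay_s, intensity = s$intensity,
               noise_sd = series_noise_sd(s))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), residue = character(),
               condition = character(), delay_s = numeric(),
               intensity = numeric(), noise_sd = numeric())
  write_tsv(df, path)
  invisible(path)
}

#' Read a relaxation-recovery table
#'
#' @param path a TSV written by [write_recovery_table].
#' @return A list of [intensity_series] with a `kind` attribute.
#' @export
read_recovery_table <- function(path) {
  df <- read_tsv(path)
  if (nrow(df) == 0) return(list())
  key <- interaction(df$kind, df$residue, df$condition, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    s <- intensity_series(g$delay_s, g$intensity, residue = g$residue[1],
                          condition = g$condition[1],
                          noise_sd = g$noise_sd[1])
    attr(s, "kind") <- g$kind[1]
    s
  })
  names(out) <- vapply(out, function(s)
    paste(attr(s, "kind"), series_residue(s), series_condition(s),
          sep = "|"), "")
  out
}

#' Write / read a study configuration
#'
#' The configuration is YAML: seed, delays and acquisition order, noise
#' levels, leakage fraction, relaxation parameters, buffer specifications
#' and (for synthetic bundles) the generating truth. Every pipeline run
#' writes its resolved configuration next to its outputs.
#'
#' @param config a named list.
#' @param path file path.
#' @return For the reader, the named list; the writer returns the path
#'   invisibly.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("seed", "delays", "noise_sd")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config is missing required fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cfg
}
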