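#' Read a perfusion sample table
#'
#' Reads the CSV sample table (comma-separated, UTF-8, "." decimal, header
#' required) and returns a validated \linkS4class{PerfusionExperiment}. Row
#' order is preserved. Unknown columns are ignored with a warning; a missing
#' mandatory column or an invalid value (negative dpm, non-positive perfusion
#' time, a token outside the closed region/species/tracer vocabularies) is an
#' error that names the offending column or row. No unit inference is
#' performed: counts must already be dpm per gram of tissue and perfusate
#' concentrations dpm per microlitre.
#'
#' @param path path to a CSV file with columns \code{sample_id, animal_id,
#'   species, region, group, treatment, tracer, Xtot_dpm_per_g,
#'   Xstar_dpm_per_g, T_s}.
#' @param perfusate the \linkS4class{PerfusateSpec} these samples were
#'   perfused with.
#' @return A \linkS4class{PerfusionExperiment}; zero samples if the file has
#'   only a header.
#' @seealso \code{\link{runPipeline}}, \code{\link{writeReport}}
#' @export
readSamples <- function(path, perfusate) {
  if (!file.exists(path)) stop("sample file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(.SAMPLE_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), .SAMPLE_COLUMNS)
  if (length(extra) > 0)
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  df <- df[, .SAMPLE_COLUMNS, drop = FALSE]
  problems <- .validateSamples(df)
  if (length(problems) > 0)
    stop("invalid sample table:\n  ", paste(problems, collapse = "\n  "))
  PerfusionExperiment(df, perfusate)
}

#' Read a perfusate key-value configuration file
#'
#' Parses a small \code{key: value} text file with keys
#' \code{Cperf_dpm_per_uL}, \code{Cstar_perf_dpm_per_uL},
#' \code{flow_rate_mL_per_min}, and optional \code{inhibitor_<name>_uM}
#' entries.
#'
#' @param path path to the configuration file.
#' @return A \linkS4class{PerfusateSpec}.
#' @export
readPerfusateSpec <- function(path) {
  if (!file.exists(path)) stop("perfusate config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_.-]+)\\s*:\\s*(.+?)\\s*$",
                                  lines))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_,
                 "")
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_,
                 "")
  if (anyNA(keys)) stop("malformed line in perfusate config")
  need <- c("Cperf_dpm_per_uL", "Cstar_perf_dpm_per_uL")
  if (!all(need %in% keys))
    stop("perfusate config must define: ", paste(need, collapse = ", "))
  getnum <- function(k, default = NA_real_) {
    if (k %in% keys) as.numeric(vals[match(k, keys)]) else default
  }
  inh_idx <- grep("^inhibitor_.*_uM$", keys)
  inhibitors <- numeric(0)
  if (length(inh_idx) > 0) {
    inhibitors <- as.numeric(vals[inh_idx])
    names(inhibitors) <- sub("^inhibitor_(.*)_uM$", "\\1", keys[inh_idx])
  }
  PerfusateSpec(Cperf = getnum("Cperf_dpm_per_uL"),
                CstarPerf = getnum("Cstar_perf_dpm_per_uL"),
                flowRate = getnum("flow_rate_mL_per_min", 10),
                inhibitors = inhibitors)
}

## Deterministic float rendering: 17 significant digits round-trips doubles
## exactly through read.csv.
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, "")
  out
}

## FNV-1a 32-bit in exact double arithmetic (all intermediates < 2^53).
.fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write per-sample results and group comparisons to disk
#'
#' Writes \code{regionpk.csv} (one row per sample, fixed column order, fixed
#' float formatting so identical inputs give byte-identical files),
#' \code{comparisons.csv} (header only when there are no comparisons), and
#' \code{run.log} recording a configuration hash and the seed. Quality flags
#' are serialized as semicolon-separated tokens in the \code{flags} column.
#'
#' @param results data.frame of per-sample results from
#'   \code{\link{runPipeline}}; must be non-empty.
#' @param comparisons data.frame of group comparisons from
#'   \code{\link{compareGroups}}, or an empty data.frame.
#' @param path output directory (created if needed).
#' @param seed the seed used for any stochastic step, recorded in the log.
#' @return Invisibly, the paths of the files written.
#' @export
writeReport <- function(results, comparisons = NULL, path, seed = NA) {
  if (is.null(results) || nrow(results) == 0)
    stop("results must be non-empty")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  pk_path <- file.path(path, "regionpk.csv")
  cmp_path <- file.path(path, "comparisons.csv")
  log_path <- file.path(path, "run.log")

  out <- results
  for (col in names(out)) if (is.numeric(out[[col]]))
    out[[col]] <- .fmtNum(out[[col]])
  con <- file(pk_path, open = "wb")
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  close(con)

  if (is.null(comparisons))
    comparisons <- emptyComparisons()
  outc <- comparisons
  for (col in names(outc)) if (is.numeric(outc[[col]]))
    outc[[col]] <- .fmtNum(outc[[col]])
  con <- file(cmp_path, open = "wb")
  utils::write.csv(outc, con, row.names = FALSE, quote = FALSE, na = "")
  close(con)

  cfg <- paste(c(names(results), dim(results), names(comparisons),
                 dim(comparisons)), collapse = "|")
  writeLines(c(sprintf("config_hash: %s", .fnv1a32(cfg)),
               sprintf("seed: %s", as.character(seed)),
               sprintf("n_samples: %d", nrow(results)),
               sprintf("n_comparisons: %d", nrow(comparisons))),
             log_path)
  invisible(c(pk_path, cmp_path, log_path))
}

#' Read back a per-sample result table
#'
#' Inverse of the \code{regionpk.csv} writer; numeric columns are restored as
#' doubles (bit-exact thanks to the 17-significant-digit formatting) and the
#' \code{flags} column is kept as semicolon-separated tokens.
#'
#' @param path path to a \code{regionpk.csv} written by
#'   \code{\link{writeReport}}.
#' @return data.frame with the same columns as the output of
#'   \code{\link{runPipeline}}.
#' @export
readRegionPK <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("T_s", "Vv", "Xtissue", "Vtissue_signed", "Vtissue", "Kin",
                "E"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  if ("flags" %in% names(df)) {
    df$flags <- ifelse(is.na(df$flags), "", df$flags)
  }
  df
}

#' @rdname readRegionPK
#' @export
readComparisons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  numcols <- c("mean_ref", "sd_ref", "n_ref", "mean_test", "sd_test",
               "n_test", "fold_change", "fold_ci_lo", "fold_ci_hi", "p_value")
  for (col in intersect(numcols, names(df))) df[[col]] <- as.numeric(df[[col]])
  df
}

## Column skeleton for an empty comparisons table (header-only CSV).
emptyComparisons <- function() {
  data.frame(stratum = character(0),
             reference_group = character(0), test_group = character(0),
             mean_ref = numeric(0), sd_ref = numeric(0), n_ref = numeric(0),
             mean_test = numeric(0), sd_test = numeric(0),
             n_test = numeric(0), fold_change = numeric(0),
             fold_ci_lo = numeric(0), fold_ci_hi = numeric(0),
             p_value = numeric(0), test_name = character(0),
             stringsAsFactors = FALSE)
}
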