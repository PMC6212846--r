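# File formats: droplet CSV, probe BED6+2, bedGraph pairs, flow-cytometry
# CSV, and JSON provenance records. All genomic coordinates are 0-based
# half-open (BED convention); strand is parsed but unused.

#' Read a probe definition file (BED6+2)
#'
#' Columns: chrom, start, end, probe_id, score (unused), strand (unused),
#' copies_per_haploid, role/allele_tag. The eighth column holds the role
#' (`target`, `early_control`, `late_control`), optionally followed by
#' `:allele` for allele-specific probes (e.g. `target:A`). Files with only
#' six columns default to `copies_per_haploid = 1` with a warning.
#'
#' @param path path to a tab-separated BED-like file (no header).
#' @return A [probe_spec()].
#' @export
read_probes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty probe file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < 6)
  if (length(bad)) {
    stop("malformed probe line ", bad[1], " (need >= 6 tab-separated ",
         "fields): ", lines[bad[1]])
  }
  get <- function(i) vapply(fields, `[`, "", i)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  badline <- which(is.na(start) | is.na(end) | start >= end)
  if (length(badline)) {
    stop("invalid interval at probe line ", badline[1], ": ",
         lines[badline[1]])
  }
  if (all(ncol >= 7)) {
    k <- suppressWarnings(as.integer(get(7)))
    if (anyNA(k)) stop("non-integer copies_per_haploid in probe file")
  } else {
    warning("no copies_per_haploid column; defaulting to 1")
    k <- rep(1L, length(lines))
  }
  role <- rep("target", length(lines))
  allele <- rep(NA_character_, length(lines))
  if (all(ncol >= 8)) {
    tag <- get(8)
    parts <- strsplit(tag, ":", fixed = TRUE)
    role <- vapply(parts, `[`, "", 1)
    allele <- vapply(parts, function(p) if (length(p) > 1) p[2]
                     else NA_character_, "")
  }
  ids <- get(4)
  if (anyDuplicated(ids)) {
    stop("duplicate probe_id in probe file: ",
         ids[duplicated(ids)][1])
  }
  probe_spec(probe_id = ids, chrom = get(1), start = start, end = end,
             copies_per_haploid = k, role = role, allele_tag = allele)
}

#' Read and write droplet-count CSV files
#'
#' Comma-separated with header; columns `sample_id`, `probe_id`,
#' `replicate_id`, `n_positive`, `n_total`, `droplet_volume_nl`.
#'
#' @param path file path.
#' @return `read_droplet_csv`: a [droplet_count()] data frame.
#' @export
read_droplet_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty droplet file: ", path)
  need <- c("sample_id", "probe_id", "replicate_id", "n_positive",
            "n_total", "droplet_volume_nl")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("droplet CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$n_positive > df$n_total)) {
    stop("n_positive > n_total in droplet file")
  }
  droplet_count(df$probe_id, df$sample_id, df$replicate_id,
                df$n_positive, df$n_total, df$droplet_volume_nl)
}

#' @rdname read_droplet_csv
#' @param counts a `droplet_count` data frame.
#' @export
write_droplet_csv <- function(counts, path) {
  cols <- c("sample_id", "probe_id", "replicate_id", "n_positive",
            "n_total", "droplet_volume_nl")
  utils::write.csv(as.data.frame(counts)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write relative copy-number values as TSV
#'
#' @param values a data frame from [baseline_normalize()] (or any data
#'   frame of per-probe values).
#' @param path output path.
#' @export
write_copy_number_tsv <- function(values, path) {
  df <- as.data.frame(values)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a replicating/non-replicating bedGraph pair into binned counts
#'
#' Both files must contain identical intervals (chrom, start, end) in the
#' same order; track/header lines are skipped.
#'
#' @param rep_path,nonrep_path bedGraph paths (chrom, start, end, count).
#' @return A [binned_counts()].
#' @export
read_bedgraph_pair <- function(rep_path, nonrep_path) {
  rd <- read_bedgraph(rep_path)
  nr <- read_bedgraph(nonrep_path)
  if (nrow(rd) != nrow(nr) ||
      !all(rd$chrom == nr$chrom & rd$start == nr$start & rd$end == nr$end)) {
    i <- which(!(rd$chrom[seq_len(min(nrow(rd), nrow(nr)))] ==
                   nr$chrom[seq_len(min(nrow(rd), nrow(nr)))] &
                 rd$start[seq_len(min(nrow(rd), nrow(nr)))] ==
                   nr$start[seq_len(min(nrow(rd), nrow(nr)))]))[1]
    stop("bedGraph pair bins disagree",
         if (!is.na(i)) sprintf(" (first mismatch: %s:%d)",
                                rd$chrom[i], rd$start[i]))
  }
  binned_counts(rd$chrom, rd$start, rd$end, rd$value, nr$value)
}

read_bedgraph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) stop("empty bedGraph: ", path)
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  df
}

#' Write a per-bin profile as bedGraph
#'
#' @param profile a data frame with `chrom`, `start`, `end` and the column
#'   named by `value_col`.
#' @param path output path.
#' @param value_col which column to write (default `adjusted_ratio`).
#' @export
write_bedgraph <- function(profile, path, value_col = "adjusted_ratio") {
  df <- data.frame(profile$chrom, profile$start, profile$end,
                   signif(profile[[value_col]], 6))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flow-cytometry summary table
#'
#' CSV with columns `sample_id`, `time_min` and `median_signal` (or
#' `mean_signal`; the column actually used is recorded in the
#' `signal_column` attribute).
#'
#' @param path file path.
#' @return A data frame with `sample_id`, `time_min`, `signal`.
#' @export
read_fc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty flow-cytometry file: ", path)
  col <- intersect(c("median_signal", "mean_signal"), names(df))[1]
  if (is.na(col)) stop("need a median_signal or mean_signal column")
  out <- data.frame(sample_id = df$sample_id, time_min = df$time_min,
                    signal = df[[col]], stringsAsFactors = FALSE)
  attr(out, "signal_column") <- col
  out
}

#' Write a JSON provenance record for a run
#'
#' Records inputs, configuration, seed and package version so a result
#' can be regenerated exactly.
#'
#' @param path output path.
#' @param inputs named list of input descriptions.
#' @param config named list of parameters (include the seed).
#' @export
write_provenance <- function(path, inputs = list(), config = list()) {
  rec <- list(
    package = "repliddpcr",
    version = as.character(utils::packageVersion("repliddpcr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    config = config
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
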