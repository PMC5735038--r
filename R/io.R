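.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wb")  # binary mode keeps Unix newlines everywhere
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write one tab-separated count table per sample
#'
#' Columns: `gene_id`, `chrom`, `start`, `end`, `strand`, `total`, `a1`,
#' `a2`. Files are named `counts_<sample_id>.tsv`; the annotation is also
#' written as BED6 (`annotation.bed`).
#'
#' @param counts an [allelic_counts()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_counts_tables <- function(counts, dir) {
  stopifnot(inherits(counts, "allelic_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in seq_len(nrow(counts$samples))) {
    df <- data.frame(counts$genes[, c("gene_id", "chrom", "start", "end",
                                      "strand")],
                     total = counts$total[, s], a1 = counts$a1[, s],
                     a2 = counts$a2[, s])
    p <- file.path(dir, paste0("counts_", counts$samples$sample_id[s], ".tsv"))
    .write_tsv(df, p)
    paths <- c(paths, p)
  }
  bed <- file.path(dir, "annotation.bed")
  write_bed(counts$genes, bed)
  invisible(c(paths, bed))
}

#' Read per-sample count tables back into an `allelic_counts` object
#'
#' Expects the layout written by [write_counts_tables()]: files
#' `counts_<condition>_rep<k>.tsv` with identical gene order.
#'
#' @param dir directory holding the tables.
#' @return an [allelic_counts()] object.
#' @export
read_counts_tables <- function(dir) {
  files <- sort(list.files(dir, pattern = "^counts_.*\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0) {
    stop("input error: no counts_*.tsv files in ", dir, call. = FALSE)
  }
  ids <- sub("^counts_(.*)\\.tsv$", "\\1", basename(files))
  m <- regmatches(ids, regexec("^(NoDox|Dox)_rep([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stop("parse error: cannot parse sample id from file ",
         basename(files[bad][1]), call. = FALSE)
  }
  samples <- data.frame(
    sample_id = ids,
    condition = vapply(m, `[`, character(1), 2),
    replicate = as.integer(vapply(m, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  o <- order(match(samples$condition, c("NoDox", "Dox")), samples$replicate)
  samples <- samples[o, , drop = FALSE]; files <- files[o]
  rownames(samples) <- NULL
  tabs <- lapply(files, .read_tsv)
  genes <- tabs[[1]][, c("gene_id", "chrom", "start", "end", "strand")]
  for (t in tabs[-1]) {
    if (!identical(t$gene_id, genes$gene_id)) {
      stop("parse error: count tables disagree on gene order", call. = FALSE)
    }
  }
  grab <- function(col) do.call(cbind, lapply(tabs, `[[`, col))
  rownames(genes) <- genes$gene_id
  allelic_counts(genes, samples, grab("total"), grab("a1"), grab("a2"))
}

#' Write a BED6 annotation file
#' @param annotation `data.frame` with `chrom`, `start`, `end`, `gene_id`
#'   (and optionally `strand`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(annotation, path) {
  strand <- if ("strand" %in% names(annotation)) annotation$strand else "."
  df <- data.frame(annotation$chrom, annotation$start, annotation$end,
                   annotation$gene_id, 0L, strand)
  con <- file(path, open = "wb"); on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a 4-column bedGraph
#' @param df `data.frame` with `chrom`, `start`, `end` and a value column.
#' @param path output path.
#' @param value_col name of the value column (default `"ddscore"`).
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(df, path, value_col = "ddscore") {
  out <- df[, c("chrom", "start", "end", value_col)]
  con <- file(path, open = "wb"); on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a repression-score table
#'
#' Tab-separated with a `# key=value` header comment line recording the
#' orientation and conditions.
#'
#' @param rs an [rs_table()]-style `data.frame`.
#' @param path file path.
#' @return invisibly, `path` (write) or the table with attributes restored
#'   (read).
#' @export
write_rs_table <- function(rs, path) {
  hdr <- sprintf("orientation=%s baseline=%s treated=%s",
                 attr(rs, "orientation") %||% "NA",
                 attr(rs, "baseline_condition") %||% "NoDox",
                 attr(rs, "treated_condition") %||% "Dox")
  .write_tsv(rs, path, comment = hdr)
}

#' @rdname write_rs_table
#' @export
read_rs_table <- function(path) {
  first <- readLines(path, n = 1)
  out <- .read_tsv(path)
  if (startsWith(first, "# ")) {
    kv <- strsplit(strsplit(sub("^# ", "", first), " ")[[1]], "=")
    for (p in kv) {
      key <- switch(p[1], orientation = "orientation",
                    baseline = "baseline_condition",
                    treated = "treated_condition", NULL)
      if (!is.null(key)) attr(out, key) <- p[2]
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ATAC track as a labelled table
#'
#' One TSV with element coordinates/state followed by `a1_<sample>` and
#' `a2_<sample>` count columns; mapped totals go in a `# mapped:` header.
#'
#' @param track an `atac_track`.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_atac_table <- function(track, path) {
  df <- track$elements
  for (s in seq_len(nrow(track$samples))) {
    id <- track$samples$sample_id[s]
    df[[paste0("a1_", id)]] <- track$a1[, s]
    df[[paste0("a2_", id)]] <- track$a2[, s]
  }
  hdr <- paste0("mapped: ", paste(sprintf("%s=%d", names(track$mapped_total),
                                          as.integer(track$mapped_total)),
                                  collapse = " "))
  .write_tsv(df, path, comment = hdr)
}

#' @rdname write_atac_table
#' @export
read_atac_table <- function(path) {
  first <- readLines(path, n = 1)
  df <- .read_tsv(path)
  a1_cols <- grep("^a1_", names(df), value = TRUE)
  ids <- sub("^a1_", "", a1_cols)
  m <- regmatches(ids, regexec("^(NoDox|Dox)_rep([0-9]+)$", ids))
  samples <- data.frame(
    sample_id = ids,
    condition = vapply(m, `[`, character(1), 2),
    replicate = as.integer(vapply(m, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  a1 <- as.matrix(df[, paste0("a1_", ids), drop = FALSE])
  a2 <- as.matrix(df[, paste0("a2_", ids), drop = FALSE])
  colnames(a1) <- colnames(a2) <- ids
  mapped <- colSums(a1) + colSums(a2)
  if (startsWith(first, "# mapped: ")) {
    kv <- strsplit(strsplit(sub("^# mapped: ", "", first), " ")[[1]], "=")
    mapped <- stats::setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
                              vapply(kv, `[`, character(1), 1))[ids]
  }
  structure(list(elements = df[, intersect(c("chrom", "start", "end", "state"),
                                           names(df)), drop = FALSE],
                 samples = samples, a1 = a1, a2 = a2, mapped_total = mapped),
            class = "atac_track")
}

#' Read a simulation scenario from a key/value config file
#'
#' The config is a Debian-control-format (DCF) file of `key: value` lines
#' whose keys are [silencing_scenario()] argument names, e.g.
#' \preformatted{
#' n_chromosomes: 5
#' transgene_chrom: chr2
#' repression_strength: 0.5
#' seed: 7
#' }
#' `chrom_lengths` may be given as `chr1:100000000,chr2:90000000`.
#' Unknown keys are a configuration error.
#'
#' @param path config file path.
#' @return a `silencing_scenario`.
#' @export
read_scenario_config <- function(path) {
  raw <- read.dcf(path)
  args <- as.list(raw[1, ])
  known <- names(formals(silencing_scenario))
  bad <- setdiff(names(args), known)
  if (length(bad)) {
    stop("configuration error: unknown scenario key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  char_keys <- c("transgene_chrom", "silenced_allele")
  for (k in names(args)) {
    if (k == "chrom_lengths") {
      parts <- strsplit(strsplit(args[[k]], ",")[[1]], ":")
      args[[k]] <- stats::setNames(as.numeric(vapply(parts, `[`, character(1), 2)),
                                   vapply(parts, `[`, character(1), 1))
    } else if (!k %in% char_keys) {
      args[[k]] <- as.numeric(args[[k]])
    }
  }
  do.call(silencing_scenario, args)
}

#' Write a run-metadata sidecar (DCF key/value)
#' @param path file path.
#' @param params named list of scalar parameters.
#' @return invisibly, `path`.
#' @export
write_run_metadata <- function(path, params) {
  params <- params[!vapply(params, is.null, logical(1))]
  m <- matrix(vapply(params, function(v) paste(format(v), collapse = ","),
                     character(1)), nrow = 1,
              dimnames = list(NULL, names(params)))
  write.dcf(m, path)
  invisible(path)
}
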