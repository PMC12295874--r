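#' Read a samples-by-features matrix from TSV
#'
#' The dialect is tab-separated UTF-8 with `.` decimals: first column holds
#' sample IDs, header holds feature IDs. Errors name the offending row or
#' column for duplicate IDs, ragged rows, or non-numeric cells.
#'
#' @param path TSV file path.
#' @param zero_var_filter drop features with zero variance across samples
#'   (removals are reported via `message()`).
#' @return Numeric matrix with sample row names and feature column names.
#' @export
read_matrix <- function(path, zero_var_filter = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 2) stop_input("matrix file '%s' has no data rows", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != widths[1])) {
    stop_input(
      "ragged row %d in '%s' (%d fields, expected %d)",
      which(widths != widths[1])[1], path, widths[widths != widths[1]][1],
      widths[1]
    )
  }
  header <- parts[[1]][-1]
  if (anyDuplicated(header)) {
    stop_input(
      "duplicated feature ID '%s' in '%s'",
      header[duplicated(header)][1], path
    )
  }
  body <- parts[-1]
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_input("duplicated sample ID '%s' in '%s'", ids[duplicated(ids)][1], path)
  }
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(length(header)))
  )
  vals <- if (length(header) == 1) matrix(vals, ncol = 1) else t(vals)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_input(
      "non-numeric cell at sample '%s', feature '%s' in '%s'",
      ids[bad[1]], header[bad[2]], path
    )
  }
  dimnames(vals) <- list(ids, header)
  if (zero_var_filter) {
    v <- apply(vals, 2, stats::var)
    drop <- colnames(vals)[v == 0]
    if (length(drop)) {
      message(sprintf(
        "removed %d zero-variance feature(s): %s", length(drop),
        paste(utils::head(drop, 10), collapse = ", ")
      ))
      vals <- vals[, v > 0, drop = FALSE]
    }
  }
  vals
}

#' Write a samples-by-features matrix as TSV
#'
#' @param x numeric matrix (or [omics_matrix()]) with dimnames.
#' @param path output path.
#' @param id_col name of the first (sample ID) column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_col = "sample") {
  x <- as_values(x)
  df <- data.frame(rownames(x), x, check.names = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read / write genomic intervals in BED format
#'
#' BED is parsed as 0-based half-open and represented in memory as a
#' `GRanges` (1-based closed, with a `name` metadata column and strand when
#' present); writing inverts the conversion losslessly.
#'
#' @param path BED file path.
#' @return `read_bed()`: a `GRanges`. `write_bed()`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(S4Vectors::mcols(gr)$name)) {
    S4Vectors::mcols(gr)$name <- paste0("iv", seq_along(gr))
  }
  if (any(BiocGenerics::width(gr) < 1)) {
    stop_input("BED interval with start >= end in '%s'", path)
  }
  gr
}

#' @param gr a `GRanges` with a `name` metadata column.
#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Headers are tokenized at the first whitespace.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  stats::setNames(as.character(ss), names(ss))
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path
  )
  invisible(path)
}

#' Read / write position weight matrices in MEME minimal format
#'
#' Probability rows whose sum is off from 1 by at most `1e-3` are
#' renormalized; rows further off are rejected with an error naming the
#' motif.
#'
#' @param path MEME minimal-format file path.
#' @return `read_meme()`: list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(lines[bg_at[1] + 1], "\\s+")[[1]]
    bg <- stats::setNames(
      as.numeric(toks[c(2, 4, 6, 8)]), toks[c(1, 3, 5, 7)]
    )[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF\\s", lines)
  if (length(starts) == 0) stop_input("no MOTIF records in '%s'", path)
  lapply(seq_along(starts), function(i) {
    name <- strsplit(lines[starts[i]], "\\s+")[[1]][2]
    at <- grep(
      "^letter-probability matrix",
      lines[starts[i]:length(lines)]
    )[1] + starts[i] - 1L
    rows <- list()
    j <- at + 1L
    while (j <= length(lines) &&
      grepl("^[0-9.eE+\\-]+(\\s+[0-9.eE+\\-]+){3}$", lines[j])) {
      rows[[length(rows) + 1]] <- as.numeric(strsplit(lines[j], "\\s+")[[1]])
      j <- j + 1L
    }
    if (length(rows) == 0) stop_input("motif '%s' has no probability rows", name)
    mat <- do.call(cbind, rows) # 4 x w, rows A C G T
    sums <- colSums(mat)
    if (any(abs(sums - 1) > 1e-3)) {
      stop_input(
        "motif '%s': probability row sums to %.4f (tolerance 1e-3)",
        name, sums[which(abs(sums - 1) > 1e-3)[1]]
      )
    }
    mat <- sweep(mat, 2, sums, "/")
    rownames(mat) <- c("A", "C", "G", "T")
    pwm(mat, name = name, background = bg)
  })
}

#' @param pwms list of [pwm()] objects.
#' @rdname read_meme
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  out <- c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]), ""
  )
  for (pw in pwms) {
    out <- c(
      out, sprintf("MOTIF %s", pw$name),
      sprintf(
        "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
        ncol(pw$mat)
      ),
      apply(pw$mat, 2, function(col) {
        sprintf("%.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])
      }),
      ""
    )
  }
  writeLines(out, path)
  invisible(path)
}

#' Write an ID-graph as a TSV edge list
#'
#' @param graph edge data frame (`parent`, `child`, `weight`).
#' @param path output path.
#' @export
write_idgraph <- function(graph, path) {
  utils::write.table(graph, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration with the study's default thresholds
#'
#' Collects every threshold of the analysis pipeline in one list, defaulting
#' to the standard settings: methylation |log2FC| >= 1 for hyper/hypo
#' labels, miRNA down-expression at log2FC <= -0.5, cis correlation screen
#' at |rho| >= 0.6 and FDR <= 0.05 within +/-1 Mbp of the TSS, miRNA-mRNA
#' screen at rho <= -0.2, motif scanning at p <= 1e-4 with enrichment cutoff
#' p <= 1e-3, 1000-draw chromatin-state resampling nulls, and 100-round
#' survival bootstrap nulls.
#'
#' @param ... overrides of individual entries.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    log2fc_meth = 1, log2fc_mirna = -0.5,
    rho_cis = 0.6, rho_mirna = -0.2, q_threshold = 0.05,
    cis_window = 1e6, motif_window = 20L,
    p_scan = 1e-4, p_enrich = 1e-3,
    n_draws = 1000L, n_bootstrap = 100L,
    survival_alpha = 0.05, cv_pearson_gate = 0.8,
    r2_threshold = 0.5,
    mcfs = mcfs_params(),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_input("unknown config entries: %s", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param cfg a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  raw <- unclass(cfg)
  raw$mcfs <- unclass(raw$mcfs)
  jsonlite::write_json(
    raw, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  mp <- raw$mcfs
  raw$mcfs <- NULL
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(mp)) {
    keep <- vapply(
      mp, function(v) length(v) == 1 && !is.na(v), logical(1)
    )
    cfg$mcfs <- do.call(mcfs_params, mp[keep])
  }
  cfg
}
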