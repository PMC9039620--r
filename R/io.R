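#' Read a differential-expression table
#'
#' Expects a tab-delimited text file with a header row. Only the three named
#' columns are used; extra columns are ignored. Rows with non-numeric fold
#' change or p-value, p-values outside (0, 1] or non-finite fold changes are
#' rejected with the offending row numbers. Duplicate gene symbols keep the
#' row with the smallest p-value (a warning reports the collapsed symbols).
#'
#' @param path path to the tab-delimited DE table
#' @param gene_col,fc_col,p_col names of the gene identifier, log2 fold
#'   change and p-value columns
#' @param dedup collapse duplicate gene symbols to their smallest-p row
#'   (default TRUE)
#' @return data frame with columns `gene_id`, `log2fc`, `pvalue`, one row per
#'   gene, in file order
#' @export
read_de_table <- function(path, gene_col = "gene", fc_col = "log2fc",
                          p_col = "pvalue", dedup = TRUE) {
  if (!file.exists(path)) stop_input("DE table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop_input("DE table is empty: %s", path)
  for (col in c(gene_col, fc_col, p_col)) {
    if (!col %in% names(df))
      stop_input("DE table lacks required column '%s' (found: %s)",
                 col, paste(names(df), collapse = ", "))
  }
  gene <- trimws(df[[gene_col]])
  # comma decimals are not a dialect we accept; as.numeric() yields NA for them
  fc <- suppressWarnings(as.numeric(df[[fc_col]]))
  p <- suppressWarnings(as.numeric(df[[p_col]]))
  bad <- which(is.na(fc) | is.na(p) | !is.finite(fc) |
                 p <= 0 | p > 1 | gene == "")
  if (length(bad) > 0L)
    stop_input("invalid DE rows (non-numeric, p outside (0,1], or empty gene): %s",
               paste(bad, collapse = ", "))
  out <- data.frame(gene_id = gene, log2fc = fc, pvalue = p,
                    stringsAsFactors = FALSE)
  if (dedup && anyDuplicated(out$gene_id)) {
    dups <- unique(out$gene_id[duplicated(out$gene_id)])
    warning(sprintf("duplicate gene symbols collapsed to smallest p-value: %s",
                    paste(dups, collapse = ", ")), call. = FALSE)
    keep <- !logical(nrow(out))
    for (g in dups) {
      idx <- which(out$gene_id == g)
      keep[idx[-which.min(out$pvalue[idx])]] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated, field 1 the set id/name,
#' field 2 a description (kept as the source label), fields 3+ the gene
#' members. Genes are upper-cased and de-duplicated on load; original ids are
#' preserved. A `pag_type` is parsed from a trailing " [P]"/" [A]"/" [G]"
#' marker on the description if present, defaulting to "P".
#'
#' @param path path to a GMT file
#' @return list of PAG records; each has `pag_id`, `name`, `source`,
#'   `pag_type` and `genes` (upper-cased, unique character vector)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("GMT file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_input("GMT file is empty: %s", path)
  seen <- character(0)
  pags <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(trimws(fields))]
    if (length(fields) < 3L)
      stop_input("GMT line %d has fewer than 3 fields (id, description, genes...)", i)
    id <- trimws(fields[[1]])
    if (id %in% seen) stop_input("duplicate PAG id '%s' at GMT line %d", id, i)
    seen <- c(seen, id)
    desc <- trimws(fields[[2]])
    type <- "P"
    m <- regmatches(desc, regexec("\\[([PAG])\\]$", desc))[[1]]
    if (length(m) == 2L) {
      type <- m[[2]]
      desc <- trimws(sub("\\[[PAG]\\]$", "", desc))
    }
    genes <- unique(toupper(trimws(fields[-(1:2)])))
    pags[[i]] <- list(pag_id = id, name = id, source = desc,
                      pag_type = type, genes = genes)
  }
  pags
}

#' Write a PAG collection as GMT
#'
#' Inverse of [read_gmt()]: round-tripping reproduces identical ids, sources
#' and gene sets.
#'
#' @param pags list of PAG records
#' @param path output path
#' @export
write_gmt <- function(pags, path) {
  lines <- vapply(pags, function(p) {
    paste(c(p$pag_id, p$source, p$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a local citation-count table
#'
#' Offline stand-in for live PubMed queries: a TSV with columns `keyword`,
#' `n` (citations of the keyword) and `k` (joint citations of the disease and
#' the keyword). The background totals N (all "disease" citations) and K
#' (citations of the specific disease) are scalars supplied separately.
#'
#' @param path path to the TSV
#' @return data frame with columns `keyword`, `n`, `k`
#' @export
read_citation_table <- function(path) {
  if (!file.exists(path)) stop_input("citation table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c("keyword", "n", "k")) {
    if (!col %in% names(df))
      stop_input("citation table lacks column '%s'", col)
  }
  if (anyDuplicated(df$keyword)) {
    dups <- unique(df$keyword[duplicated(df$keyword)])
    stop_input("duplicate keyword(s) in citation table: %s",
               paste(dups, collapse = ", "))
  }
  n <- suppressWarnings(as.numeric(df$n))
  k <- suppressWarnings(as.numeric(df$k))
  if (anyNA(n) || anyNA(k)) stop_input("non-numeric counts in citation table")
  if (any(n < 0) || any(k < 0)) stop_input("negative counts in citation table")
  bad <- which(k > n)
  if (length(bad) > 0L)
    stop_input("k > n for keyword(s): %s",
               paste(df$keyword[bad], collapse = ", "))
  data.frame(keyword = df$keyword, n = as.integer(n), k = as.integer(k),
             stringsAsFactors = FALSE)
}

#' Read per-tool enrichment term lists
#'
#' Each file is a TSV with columns `term` and `adjusted_p`; the tool id is
#' the name given in `paths` (or the file's base name).
#'
#' @param paths named character vector of file paths; names are tool ids
#' @return named list of data frames (term, adjusted_p)
#' @export
read_term_lists <- function(paths) {
  ids <- names(paths)
  if (is.null(ids)) {
    ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  out <- lapply(seq_along(paths), function(i) {
    df <- utils::read.delim(paths[[i]], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (!all(c("term", "adjusted_p") %in% names(df)))
      stop_input("term list %s lacks columns term, adjusted_p", paths[[i]])
    if (any(is.na(df$term)) || any(!nzchar(trimws(df$term))))
      stop_input("empty term string in %s", paths[[i]])
    df[c("term", "adjusted_p")]
  })
  stats::setNames(out, ids)
}
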