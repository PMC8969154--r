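# Plain-text readers/writers: expression TSV + sample metadata, GMT gene
# sets, long quant CSVs, melting-curve CSV, JSON results. All formats
# round-trip losslessly.

#' Read an expression matrix and its sample metadata
#'
#' @param path_values TSV, genes in rows (first column `gene_id`), one column
#'   per sample.
#' @param path_meta TSV with columns `sample_id` and `tumor` (logical or
#'   0/1), covering every sample in the value file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path_values, path_meta) {
  vals <- utils::read.delim(path_values, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(names(vals)[1] == "gene_id", "first column of the value file must be gene_id")
  assert_that(!anyDuplicated(vals$gene_id), "duplicated gene ids in value file")
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$gene_id
  meta <- utils::read.delim(path_meta, stringsAsFactors = FALSE)
  meta$tumor <- as.logical(meta$tumor)
  expression_matrix(m, meta)
}

#' Write an expression matrix and its sample metadata
#' @param expr An [expression_matrix()].
#' @param path_values,path_meta Output TSV paths.
#' @export
write_expression <- function(expr, path_values, path_meta) {
  stopifnot(inherits(expr, "expr_matrix"))
  # %.17g preserves doubles exactly across the write/read round-trip
  fmt <- apply(expr$values, 2, function(x) sprintf("%.17g", x))
  df <- data.frame(gene_id = rownames(expr$values), fmt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(expr$values))
  utils::write.table(df, path_values, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$sample_meta, path_meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path_values, path_meta))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Duplicate members within a set are removed with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions kept as an
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), descriptions = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3)
  if (length(bad))
    stop(errorCondition(sprintf("malformed GMT line %d: need name, description and >= 1 member",
                                bad[1]),
                        class = c("acylomics_parse_error", "error")))
  sets <- lapply(parts, function(x) {
    members <- x[-(1:2)]
    if (anyDuplicated(members))
      warning(sprintf("duplicate members in set '%s' deduplicated", x[1]))
    unique(members)
  })
  names(sets) <- vapply(parts, `[`, "", 1L)
  structure(sets, descriptions = stats::setNames(vapply(parts, `[`, "", 2L), names(sets)))
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (default `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    d <- if (nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a long acyl-peptide quantification CSV
#'
#' Columns: `peptide_seq, site_residue, mod_type, condition, replicate,
#' intensity`; empty intensity cells are missing values.
#'
#' @param path CSV path.
#' @return Validated long data.frame.
#' @export
read_acyl_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$site_residue <- as.integer(tab$site_residue)
  tab$intensity <- as.numeric(tab$intensity)
  check_acyl_table(tab)
}

#' Write a long acyl-peptide quantification CSV
#' @param table Long acyl-peptide table.
#' @param path Output path.
#' @export
write_acyl_table <- function(table, path) {
  table$intensity <- ifelse(is.na(table$intensity), "",
                            sprintf("%.17g", table$intensity))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a melting curve CSV (`temp_c, signal`)
#' @param path CSV path.
#' @return A `melting_curve` data.frame.
#' @export
read_melting_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_melting_curve(df)
  structure(df[, c("temp_c", "signal")], class = c("melting_curve", "data.frame"))
}

#' Read an activity trace CSV (`time_s, a600`)
#' @param path CSV path.
#' @param eps_mM_cm,path_cm,volume_ml,protein_mg Assay constants to attach.
#' @return An `activity_trace` data.frame.
#' @export
read_activity_trace <- function(path, eps_mM_cm = 21, path_cm = 1,
                                volume_ml = 1, protein_mg = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("time_s", "a600") %in% names(df)), "trace needs time_s and a600 columns")
  structure(df, eps_mM_cm = eps_mM_cm, path_cm = path_cm, volume_ml = volume_ml,
            protein_mg = protein_mg, class = c("activity_trace", "data.frame"))
}

#' Read a long metabolite table CSV (`metabolite, group, replicate, area`)
#' @param path CSV path.
#' @return Long data.frame.
#' @export
read_metabolite_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("metabolite", "group", "replicate", "area") %in% names(tab)),
              "table needs metabolite, group, replicate, area columns")
  tab
}

#' Write a query result to TSV
#' @param res A [query_top()] result.
#' @param path Output path.
#' @export
write_query_result <- function(res, path) {
  stopifnot(inherits(res, "query_result"))
  utils::write.table(res$ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write any result list to JSON
#' @param x A list (e.g. a `corr_null` or `two_state_fit`).
#' @param path Output path.
#' @export
write_json_result <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
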