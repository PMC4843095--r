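# Plain-text readers/writers for the pipeline's interchange formats:
# counts TSV (genes x samples), sample sheet CSV, spectrum report CSV,
# results TSV, module model JSON.

#' @rdname rootheat_io
#' @param counts gene x sample integer matrix.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write pipeline interchange files
#'
#' Counts are genes x samples TSV with a `gene_id` column; sample sheets
#' and spectrum reports are plain CSV. Validation failures name the
#' missing column.
#'
#' @name rootheat_io
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  assert_that("gene_id" %in% names(df), "counts TSV needs a gene_id column")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' @rdname rootheat_io
#' @param design sample sheet data frame.
#' @export
write_design_csv <- function(design, path) {
  write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname rootheat_io
#' @export
read_design_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  needed <- c("sample", "tissue", "treatment", "time_h", "replicate",
              "plate", "libsize")
  missing <- setdiff(needed, names(df))
  assert_that(length(missing) == 0,
              paste("sample sheet is missing column(s):",
                    paste(missing, collapse = ", ")))
  df
}

#' @rdname rootheat_io
#' @param spectra spectrum report tibble.
#' @export
write_spectra_csv <- function(spectra, path) {
  write.csv(spectra, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname rootheat_io
#' @export
read_spectra_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  needed <- c("scan", "peptide", "protein", "plex", "fraction",
              "base_peak", paste0("ch", 1:8))
  missing <- setdiff(needed, names(df))
  assert_that(length(missing) == 0,
              paste("spectrum report is missing column(s):",
                    paste(missing, collapse = ", ")))
  df
}

#' @rdname rootheat_io
#' @param net a `module_network`.
#' @export
write_module_json <- function(net, path) {
  jsonlite::write_json(
    list(k = net$k,
         total_loglik = net$total_loglik,
         history = net$history,
         trees = lapply(net$modules, tree_to_list),
         assignment = as.list(net$assignment)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

tree_to_list <- function(tree) {
  if (is_leaf(tree))
    return(list(leaf = TRUE, conditions = as.list(tree$conditions),
                mu = tree$mu, sigma2 = tree$sigma2))
  list(leaf = FALSE, tf = tree$tf, query = tree$query,
       yes = tree_to_list(tree$yes), no = tree_to_list(tree$no))
}
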