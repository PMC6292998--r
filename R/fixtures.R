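# Published connection-record fixtures shipped with the package.

#' The 42 published connection records
#'
#' The three printed tables of connection records between brain-structure
#' pairs from the NKI Rockland averaged connectivity joined with Allen-atlas
#' differential expression: table 1 holds the 25 putamen-originating
#' high-DEG connections, table 2 the 8 functionally connected high-DEG
#' pairs, table 3 the 9 strongly connected pairs with near-homogeneous
#' expression. Duplicate rows (several coordinates sharing labels) are
#' preserved.
#'
#' @param table optional subset: 1, 2 or 3.
#' @return data.frame with columns \code{table}, \code{origin},
#'   \code{target}, \code{structural}, \code{functional}, \code{deg_avg};
#'   42 rows in total.
#' @export
paper_tables_fixture <- function(table = NULL) {
  path <- system.file("extdata", "connection_tables.tsv",
                      package = "connectomekb", mustWork = TRUE)
  rec <- utils::read.delim(path, quote = "", stringsAsFactors = FALSE)
  if (!is.null(table)) rec <- rec[rec$table %in% table, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
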