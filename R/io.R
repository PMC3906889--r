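# Tab-separated table schemas. One dialect everywhere: UTF-8 TSV, "NA" for
# missing values, a '#' comment header carrying the package version, the
# seed and a config hash so every output states its provenance.

.tsvHeader <- function(seed = NULL, config = NULL) {
  h <- sprintf("# package: qhtcp %s",
               as.character(utils::packageVersion("qhtcp")))
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(config)) h <- c(h, sprintf("# config_hash: %s",
                                          rlang::hash(config)))
  h
}

# full-precision serialization of numeric columns so round-trips are exact
.writeTsv <- function(df, path, seed = NULL, config = NULL) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.tsvHeader(seed, config), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.readTsv <- function(path, required, numericCols = character()) {
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE, fill = FALSE, na.strings = "NA"),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e))
  )
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("'", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (cn in intersect(numericCols, names(df))) df[[cn]] <- as.numeric(df[[cn]])
  df
}

#' Read and write per-culture time series tables
#'
#' Long TSV with columns `culture_id`, `time_h`, `intensity`.
#'
#' @param seriesList list of [CultureSeries].
#' @param path file path.
#' @param seed,config optional provenance recorded in the file header.
#' @return `writeTimeSeriesTable` returns the path invisibly;
#'   `readTimeSeriesTable` returns a named list of [CultureSeries].
#' @export
writeTimeSeriesTable <- function(seriesList, path, seed = NULL, config = NULL) {
  df <- do.call(rbind, lapply(seriesList, function(s)
    data.frame(culture_id = cultureId(s), time_h = obsTimes(s),
               intensity = intensities(s))))
  .writeTsv(df, path, seed, config)
}

#' @rdname writeTimeSeriesTable
#' @export
readTimeSeriesTable <- function(path) {
  df <- .readTsv(path, c("culture_id", "time_h", "intensity"),
                 c("time_h", "intensity"))
  ids <- unique(df$culture_id)
  stats::setNames(lapply(ids, function(id) {
    sub <- df[df$culture_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    CultureSeries(id, sub$time_h, sub$intensity)
  }), ids)
}

.screenCols <- c("oligomycin", "orf", "gene", "auc", "K", "r", "L",
                 "r_squared", "K_lower", "K_upper", "r_lower", "r_upper",
                 "L_lower", "L_upper")

#' Read and write screen-layout growth-parameter tables
#'
#' One row per culture: oligomycin concentration, ORF and gene names, AUC,
#' the logistic parameters `K`, `r`, `L`, the fit's R-squared, and the six
#' 95% confidence-bound columns.
#'
#' @param df data.frame with the screen columns (extra columns are kept).
#' @param path file path.
#' @param seed,config optional provenance recorded in the file header.
#' @export
writeScreenTable <- function(df, path, seed = NULL, config = NULL) {
  missing <- setdiff(.screenCols, names(df))
  if (length(missing))
    stop("screen table is missing column(s): ", paste(missing, collapse = ", "))
  .writeTsv(df[, c(.screenCols, setdiff(names(df), .screenCols)), drop = FALSE],
            path, seed, config)
}

#' @rdname writeScreenTable
#' @export
readScreenTable <- function(path) {
  .readTsv(path, .screenCols, setdiff(.screenCols, c("orf", "gene")))
}

.interactionCols <- c("orf", "gene", "orf_effect", "interaction",
                      "n_no_growth")

#' Read and write interaction-layout tables
#'
#' One row per deletion strain: ORF and gene names, the ORF effect (`K0`,
#' the zero-dose difference from the reference median), the interaction
#' value at the highest grown dose, and the number of high concentrations
#' with no growth.
#'
#' @param df data.frame with the interaction columns (extras kept).
#' @param path file path.
#' @param seed,config optional provenance recorded in the file header.
#' @export
writeInteractionTable <- function(df, path, seed = NULL, config = NULL) {
  missing <- setdiff(.interactionCols, names(df))
  if (length(missing))
    stop("interaction table is missing column(s): ",
         paste(missing, collapse = ", "))
  .writeTsv(df[, c(.interactionCols,
                   setdiff(names(df), .interactionCols)), drop = FALSE],
            path, seed, config)
}

#' @rdname writeScreenTable
#' @export
readInteractionTable <- function(path) {
  .readTsv(path, .interactionCols,
           c("orf_effect", "interaction", "n_no_growth"))
}

#' Read and write interaction-profile matrices
#'
#' Genes x perturbation-column TSV in the A-O schema; `NA` entries are
#' masked (and median-imputed by [remc]).
#'
#' @param profiles an [InteractionProfiles].
#' @param path file path.
#' @param seed,config optional provenance recorded in the file header.
#' @export
writeProfilesTable <- function(profiles, path, seed = NULL, config = NULL) {
  X <- profileValues(profiles)
  X[!profileMask(profiles)] <- NA_real_
  df <- data.frame(gene = rownames(X), X, check.names = FALSE)
  .writeTsv(df, path, seed, config)
}

#' @rdname writeProfilesTable
#' @export
readProfilesTable <- function(path) {
  df <- .readTsv(path, "gene")
  X <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- df$gene
  InteractionProfiles(X)
}

#' Read gene-set annotations
#'
#' Two-column TSV (`term_id`, `gene_id`), one row per term-gene pairing.
#'
#' @param path file path.
#' @return named list mapping term id to a character vector of gene ids.
#' @export
readGeneSets <- function(path) {
  df <- .readTsv(path, c("term_id", "gene_id"))
  split(df$gene_id, df$term_id)
}

#' @rdname readGeneSets
#' @param geneSets named list term -> genes.
#' @param seed,config optional provenance recorded in the file header.
#' @export
writeGeneSets <- function(geneSets, path, seed = NULL, config = NULL) {
  df <- data.frame(
    term_id = rep(names(geneSets), lengths(geneSets)),
    gene_id = unlist(geneSets, use.names = FALSE)
  )
  .writeTsv(df, path, seed, config)
}

#' Write a cluster summary table
#'
#' One row per leaf cluster: id, size, log-likelihood, aggregate enrichment
#' z and the number of enriched terms (adjusted p below `alpha`).
#'
#' @param df data.frame with columns `cluster`, `size`, `log_lik`,
#'   `goid_z`, `n_enriched_terms`.
#' @param path file path.
#' @param seed,config optional provenance recorded in the file header.
#' @export
writeClusterSummary <- function(df, path, seed = NULL, config = NULL) {
  required <- c("cluster", "size", "log_lik", "goid_z", "n_enriched_terms")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cluster summary is missing column(s): ",
         paste(missing, collapse = ", "))
  .writeTsv(df, path, seed, config)
}

#' @rdname writeClusterSummary
#' @export
readClusterSummary <- function(path) {
  .readTsv(path, c("cluster", "size", "log_lik", "goid_z",
                   "n_enriched_terms"),
           c("size", "log_lik", "goid_z", "n_enriched_terms"))
}
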