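#' @importFrom stats cor cor.test dist p.adjust quantile rbinom rlnorm rmultinom
#'   rnorm runif sd setNames wilcox.test complete.cases isoreg median plogis
#' @importFrom utils combn read.delim write.table head
NULL

KINGDOMS <- c("bacteria", "fungi")
COMPOUND_CLASSES <- c("ester", "acid", "alcohol", "aldehyde", "phenol",
                      "amino_acid", "organic_acid", "physicochemical")

#' Construct an abundance table
#'
#' A taxa-by-samples matrix of non-negative abundances with a kingdom label
#' (bacteria or fungi) per taxon. Row names are taxon names, column names are
#' sample ids.
#'
#' @param values numeric matrix, taxa in rows, samples in columns; row and
#'   column names required, entries non-negative.
#' @param kingdom character vector, one of `"bacteria"`/`"fungi"` per taxon,
#'   named by taxon or in row order.
#' @return An object of class `abundance_table`: a list with elements
#'   `values` (the matrix) and `kingdom` (named character vector).
#' @export
abundance_table <- function(values, kingdom) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs taxon row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated taxon names: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids in abundance table")
  if (!is.numeric(values) || anyNA(values))
    stop("abundance values must be numeric and non-missing")
  if (any(values < 0)) stop("abundance values must be non-negative")
  if (is.null(names(kingdom))) names(kingdom) <- rownames(values)
  kingdom <- kingdom[rownames(values)]
  if (anyNA(kingdom) || !all(kingdom %in% KINGDOMS))
    stop("unknown kingdom label; allowed: ", paste(KINGDOMS, collapse = ", "))
  structure(list(values = values, kingdom = kingdom), class = "abundance_table")
}

#' Construct a compound table
#'
#' A compounds-by-samples matrix of concentrations with a chemical class per
#' compound (ester, acid, alcohol, aldehyde, phenol, amino_acid,
#' organic_acid, or physicochemical).
#'
#' @param values numeric matrix, compounds in rows, samples in columns.
#' @param compound_class character vector of class labels per compound.
#' @return An object of class `compound_table` with elements `values` and
#'   `compound_class`.
#' @export
compound_table <- function(values, compound_class) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("compound matrix needs compound row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated compound names")
  if (!is.numeric(values) || anyNA(values))
    stop("compound values must be numeric and non-missing (no NA imputation)")
  if (is.null(names(compound_class))) names(compound_class) <- rownames(values)
  compound_class <- compound_class[rownames(values)]
  if (anyNA(compound_class) || !all(compound_class %in% COMPOUND_CLASSES))
    stop("unknown compound_class label; allowed: ",
         paste(COMPOUND_CLASSES, collapse = ", "))
  structure(list(values = values, compound_class = compound_class),
            class = "compound_table")
}

#' Construct sample metadata
#'
#' @param df data frame with columns `sample_id`, `group`, `day`
#'   (non-negative integer fermentation day) and `replicate` (positive
#'   integer).
#' @return A validated `sample_metadata` data frame.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "group", "day", "replicate")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  if (anyNA(df$day) || any(df$day < 0) || any(df$day != round(df$day)))
    stop("day must be a non-negative integer")
  if (anyNA(df$replicate) || any(df$replicate < 1) ||
      any(df$replicate != round(df$replicate)))
    stop("replicate must be a positive integer")
  key <- paste(df$group, df$day, df$replicate)
  if (anyDuplicated(key))
    stop("duplicated (group, day, replicate) triple: ",
         key[duplicated(key)][1])
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$values), "taxa x", ncol(x$values), "samples (",
      sum(x$kingdom == "bacteria"), "bacteria,", sum(x$kingdom == "fungi"),
      "fungi )\n")
  invisible(x)
}

#' @export
print.compound_table <- function(x, ...) {
  cat("compound_table:", nrow(x$values), "compounds x", ncol(x$values),
      "samples\n")
  print(table(x$compound_class))
  invisible(x)
}

samples_of <- function(x) colnames(x$values)

read_annotated_tsv <- function(path, key_name, annot_name) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 3)
    stop(path, ": expected key column, ", annot_name,
         " column and at least one sample column")
  keys <- raw[[1]]
  annot <- raw[[2]]
  vals <- raw[, -(1:2), drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(path, ": non-numeric cell at row '", keys[bad[1, 1]], "', column '",
         colnames(vals)[bad[1, 2]], "'")
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(path, ": missing value at row '", keys[bad[1, 1]], "', column '",
         colnames(vals)[bad[1, 2]], "'")
  }
  rownames(num) <- keys
  names(annot) <- keys
  list(values = num, annot = annot)
}

#' Read an abundance TSV
#'
#' Expected layout: header row; column 1 = taxon name, column 2 = kingdom
#' label, remaining columns = samples.
#' @param path path to a tab-delimited file.
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path) {
  x <- read_annotated_tsv(path, "taxon", "kingdom")
  abundance_table(x$values, x$annot)
}

#' Read a compound TSV
#'
#' Column 1 = compound name, column 2 = compound_class, remaining columns =
#' samples.
#' @param path path to a tab-delimited file.
#' @return a [compound_table()].
#' @export
read_compounds <- function(path) {
  x <- read_annotated_tsv(path, "compound", "compound_class")
  compound_table(x$values, x$annot)
}

#' Read a sample-metadata TSV
#' @param path path to a tab-delimited file with columns sample_id, group,
#'   day, replicate.
#' @return a [sample_metadata()] data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Write an abundance or compound table as TSV
#'
#' Inverse of [read_abundance()] / [read_compounds()]; full double precision
#' is retained so a write/read round trip reproduces values.
#' @param x an `abundance_table` or `compound_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  if (inherits(x, "abundance_table")) {
    df <- data.frame(taxon = rownames(x$values), kingdom = unname(x$kingdom),
                     x$values, check.names = FALSE, stringsAsFactors = FALSE)
  } else if (inherits(x, "compound_table")) {
    df <- data.frame(compound = rownames(x$values),
                     compound_class = unname(x$compound_class),
                     x$values, check.names = FALSE, stringsAsFactors = FALSE)
  } else if (inherits(x, "sample_metadata")) {
    df <- as.data.frame(x)
  } else stop("unsupported table type")
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load and cross-validate the three input tables
#'
#' Reads the abundance, compound and metadata TSVs, checks that all three
#' share one sample universe, and reorders the table columns to the metadata
#' sample order.
#'
#' @param abundance_path,compound_path,metadata_path file paths.
#' @return list with elements `abundance`, `compounds`, `metadata`.
#' @export
load_dataset <- function(abundance_path, compound_path, metadata_path) {
  abund <- read_abundance(abundance_path)
  comp <- read_compounds(compound_path)
  meta <- read_metadata(metadata_path)
  harmonize_samples(abund, comp, meta)
}

#' Harmonize already-constructed tables to the metadata sample order
#' @param abund abundance_table; @param comp compound_table;
#' @param meta sample_metadata.
#' @return list(abundance, compounds, metadata)
#' @export
harmonize_samples <- function(abund, comp, meta) {
  want <- meta$sample_id
  for (tb in list(abundance = abund, compounds = comp)) {
    have <- samples_of(tb)
    miss <- setdiff(want, have)
    extra <- setdiff(have, want)
    if (length(miss) || length(extra))
      stop("sample-set mismatch; missing from table: [",
           paste(miss, collapse = ", "), "]; absent from metadata: [",
           paste(extra, collapse = ", "), "]")
  }
  abund$values <- abund$values[, want, drop = FALSE]
  comp$values <- comp$values[, want, drop = FALSE]
  list(abundance = abund, compounds = comp, metadata = meta)
}

#' Convert an abundance table to relative abundances
#'
#' Each sample column is divided by its sum, so columns sum to 1. Idempotent
#' and invariant to per-sample scaling; zero entries stay zero.
#'
#' @param table an `abundance_table` with at least one positive entry per
#'   sample.
#' @return an `abundance_table` of proportions.
#' @export
to_relative_abundance <- function(table) {
  cs <- colSums(table$values)
  zero <- which(cs <= 0)
  if (length(zero))
    stop("all-zero sample column: ", colnames(table$values)[zero[1]])
  table$values <- sweep(table$values, 2, cs, "/")
  table
}
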