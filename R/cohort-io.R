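#' Cohort table: subjects x regions thickness plus covariates
#'
#' The raw input of the pipeline: one row per subject, a matrix of regional
#' mean cortical thickness (mm), a two-level group factor and per-subject
#' numeric nuisance covariates. If a `mean_thickness` covariate is absent it
#' is computed as the row mean of the thickness matrix.
#'
#' @param thickness numeric matrix, subjects x regions, with unique region
#'   column names and subject row names. Strictly positive, finite.
#' @param group factor (or coercible) with exactly two levels; each level
#'   must contain at least 3 subjects for Pearson correlation downstream.
#' @param covariates data.frame of numeric per-subject covariates.
#' @param subject_id character vector of unique subject identifiers.
#' @param residualized logical; residual tables (centered around 0, possibly
#'   negative) skip the positivity check.
#' @return object of class `cohort_table`.
#' @export
cohort_table <- function(thickness, group, covariates = NULL,
                         subject_id = rownames(thickness),
                         residualized = FALSE) {
  thickness <- as.matrix(thickness)
  storage.mode(thickness) <- "double"
  if (is.null(subject_id)) subject_id <- paste0("S", seq_len(nrow(thickness)))
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id))
    stop("duplicated subject id: ",
         paste(unique(subject_id[duplicated(subject_id)]), collapse = ", "))
  rownames(thickness) <- subject_id
  group <- droplevels(as.factor(group))
  if (is.null(covariates)) covariates <- data.frame(row.names = subject_id)
  covariates <- as.data.frame(covariates, row.names = subject_id)
  x <- structure(
    list(subject_id = subject_id, group = group, thickness = thickness,
         covariates = covariates),
    residualized = residualized, class = "cohort_table")
  validate_cohort(x)
}

#' Validate a cohort table against its invariants
#'
#' Checks positivity and finiteness of thickness, uniqueness of subject and
#' region identifiers, the two-group requirement (>= 3 subjects per group),
#' numeric covariates, and fills in the `mean_thickness` covariate when it is
#' missing.
#'
#' @param x a `cohort_table`.
#' @return the validated (possibly augmented) `cohort_table`, invisibly
#'   usable in pipelines.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort_table"))
  th <- x$thickness
  if (anyDuplicated(x$subject_id))
    stop("duplicated subject id: ",
         paste(unique(x$subject_id[duplicated(x$subject_id)]), collapse = ", "))
  if (is.null(colnames(th)) || anyDuplicated(colnames(th)))
    stop("region names must be present and unique")
  bad <- which(!is.finite(th), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("missing or non-numeric thickness: subject ",
         x$subject_id[bad[1, 1]], ", region ", colnames(th)[bad[1, 2]])
  if (!isTRUE(attr(x, "residualized")) && any(th <= 0)) {
    bad <- which(th <= 0, arr.ind = TRUE)
    stop("thickness must be strictly positive: subject ",
         x$subject_id[bad[1, 1]], ", region ", colnames(th)[bad[1, 2]])
  }
  if (nlevels(x$group) != 2)
    stop("exactly two group levels required, found ", nlevels(x$group),
         " (", paste(levels(x$group), collapse = ", "), ")")
  if (any(table(x$group) < 3))
    stop("each group needs at least 3 subjects for Pearson correlation")
  if (length(x$group) != nrow(th))
    stop("group length does not match number of subjects")
  nonnum <- names(x$covariates)[!vapply(x$covariates, is.numeric, logical(1))]
  if (length(nonnum) > 0)
    stop("non-numeric covariate column(s): ", paste(nonnum, collapse = ", "))
  if (!"mean_thickness" %in% names(x$covariates))
    x$covariates$mean_thickness <- rowMeans(th)
  x
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$thickness), "subjects x",
      ncol(x$thickness), "regions\n")
  print(table(x$group))
  cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  if (isTRUE(attr(x, "residualized"))) cat("(residualized)\n")
  invisible(x)
}

#' Region labels of a cohort, in pipeline order
#' @param cohort a `cohort_table`.
#' @return character vector of region names (the input column order, which is
#'   preserved through every downstream matrix and network).
#' @export
region_names <- function(cohort) colnames(cohort$thickness)

#' Read a wide-format cohort table from a delimited file
#'
#' One subject per row. The schema names the group column and covariate
#' columns and identifies region columns either explicitly
#' (`region_cols`) or by prefix (`region_prefix`, e.g. `c("lh_", "rh_")` for
#' a two-hemisphere parcellation export). Field separator is inferred from
#' the extension (`.tsv`/`.txt` tab, otherwise comma).
#'
#' @param path file path.
#' @param schema list with elements `group_col` (required), optional
#'   `id_col`, `covariate_cols` (character vector), and one of `region_cols`
#'   or `region_prefix`. Optional `recode` is a named list mapping a column
#'   name to a named numeric vector used to recode categorical covariates
#'   (e.g. `list(gender = c(F = 0, M = 1))`).
#' @return validated `cohort_table`; region order is the file's column order.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(schema$group_col)) stop("schema must name group_col")
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!schema$group_col %in% names(df))
    stop("group column not found: ", schema$group_col)
  for (nm in names(schema$recode %||% list())) {
    map <- schema$recode[[nm]]
    df[[nm]] <- unname(map[as.character(df[[nm]])])
  }
  if (!is.null(schema$region_cols)) {
    regions <- schema$region_cols
    missing <- setdiff(regions, names(df))
    if (length(missing) > 0)
      stop("region column(s) not found: ", paste(missing, collapse = ", "))
  } else if (!is.null(schema$region_prefix)) {
    hit <- Reduce(`|`, lapply(schema$region_prefix,
                              function(p) startsWith(names(df), p)))
    regions <- names(df)[hit]
    if (length(regions) == 0)
      stop("no columns match region prefix(es): ",
           paste(schema$region_prefix, collapse = ", "))
  } else stop("schema must give region_cols or region_prefix")
  covs <- schema$covariate_cols %||% character()
  missing <- setdiff(covs, names(df))
  if (length(missing) > 0)
    stop("covariate column(s) not found: ", paste(missing, collapse = ", "))
  ids <- if (!is.null(schema$id_col)) as.character(df[[schema$id_col]])
         else paste0("S", seq_len(nrow(df)))
  th <- as.matrix(df[, regions, drop = FALSE])
  if (!is.numeric(th)) {
    badcol <- regions[!vapply(df[, regions, drop = FALSE], is.numeric, logical(1))][1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[badcol]]))))[1]
    stop("non-numeric thickness: subject ", ids[badrow], ", region ", badcol)
  }
  cohort_table(th, df[[schema$group_col]],
               df[, covs, drop = FALSE], subject_id = ids)
}

#' Write a cohort table to a delimited file
#'
#' Full-precision text output; `read_cohort` with the matching schema
#' recovers the table exactly (up to the text round-trip, which is
#' bit-identical for doubles at 17 significant digits).
#'
#' @param cohort a `cohort_table`.
#' @param path output path; extension chooses the separator as in
#'   [read_cohort()].
#' @return the schema (list) that reads the file back, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  covs <- cohort$covariates
  header <- c("subject_id", "group", names(covs), region_names(cohort))
  rows <- cbind(cohort$subject_id, as.character(cohort$group),
                do.call(cbind, c(lapply(covs, .fmt_num), list(deparse.level = 0))),
                matrix(.fmt_num(cohort$thickness), nrow = nrow(cohort$thickness)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  writeLines(apply(rows, 1, paste, collapse = sep), con)
  invisible(list(group_col = "group", id_col = "subject_id",
                 covariate_cols = names(covs),
                 region_cols = region_names(cohort)))
}

#' Write a labeled square matrix as delimited text
#'
#' @param matrix square numeric matrix.
#' @param path output path.
#' @param labels row/column labels; defaults to the matrix's own dimnames.
#' @return `path`, invisibly. The file has a header row and a leading label
#'   column and round-trips bit-identically through [read_matrix()].
#' @export
write_matrix <- function(matrix, path, labels = rownames(matrix)) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(m)))
  if (length(labels) != nrow(m))
    stop("labels length (", length(labels), ") does not match matrix dimension (",
         nrow(m), ")")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("region", labels), collapse = ","), con)
  body <- matrix(.fmt_num(m), nrow = nrow(m))
  writeLines(paste(labels, apply(body, 1, paste, collapse = ","), sep = ","), con)
  invisible(path)
}

#' Read a labeled square matrix written by [write_matrix()]
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  colnames(m) <- colnames(df)
  m
}
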