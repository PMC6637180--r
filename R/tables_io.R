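#' Construct an abundance table
#'
#' The canonical container for a samples x features matrix of non-negative
#' relative abundances (or raw counts prior to normalization).  Rows are
#' always samples in memory, whatever the orientation of the file the values
#' came from.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids,feature_ids Character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @param normalized Logical; `TRUE` declares that every row sums to 1
#'   (total-sum scaled).  Validated on construction.
#' @return An object of class `abundance_table` with elements `values`
#'   (named matrix) and `normalized`.
#' @seealso [tss_normalize()], [read_abundance_table()]
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            feature_ids = colnames(values),
                            normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(sample_ids), as.character(feature_ids))
  out <- structure(list(values = values, normalized = isTRUE(normalized)),
                   class = "abundance_table")
  validate_abundance_table(out)
}

#' Validate an abundance table
#'
#' Checks the container invariants: all values finite and non-negative, no
#' duplicated sample or feature identifiers, and (when flagged normalized)
#' every row sum within 1e-8 of 1.
#'
#' @param x An `abundance_table`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_abundance_table <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  v <- x$values
  if (anyDuplicated(rownames(v)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate feature identifiers: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at sample '%s', feature '%s'",
                 rownames(v)[bad[1]], colnames(v)[bad[2]]))
  }
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value %g at sample '%s', feature '%s'",
                 v[bad[1], bad[2]], rownames(v)[bad[1]], colnames(v)[bad[2]]))
  }
  if (x$normalized) {
    rs <- rowSums(v)
    off <- which(abs(rs - 1) > 1e-8)
    if (length(off))
      stop("table flagged normalized but row sums deviate from 1 for sample(s): ",
           paste(rownames(v)[utils::head(off, 5)], collapse = ", "))
  }
  x
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "relative abundances, rows sum to 1"
              else "not normalized"))
  invisible(x)
}

#' @rdname abundance_table
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname abundance_table
#' @export
feature_ids <- function(x) colnames(x$values)

#' @export
dim.abundance_table <- function(x) dim(x$values)

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2)
    stop("expected a tab-delimited file with an ID column and at least one data column: ", path)
  ids <- df[[1]]
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, colnames(df)[-1]))
  for (j in seq_len(ncol(m))) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(trimws(raw) %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                   raw[bad[1]], ids[bad[1]], colnames(m)[j], path))
    if (anyNA(num))
      stop(sprintf("missing cell at row '%s', column '%s' in %s (tables are dense; zeros must be explicit)",
                   ids[which(is.na(num))[1]], colnames(m)[j], path))
    m[, j] <- num
  }
  m
}

#' Read an abundance table from a tab-delimited file
#'
#' The file has one header row and one leading ID column.  Both orientations
#' found in microbiome tooling are supported; in memory rows are always
#' samples.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param orientation `"samples_in_rows"` (ID column `sample_id`, features in
#'   columns; the default file convention), `"features_in_rows"` (transposed),
#'   or `"auto"`, which trusts a first header cell literally equal to
#'   `"sample_id"` or `"feature_id"` and otherwise assumes samples in rows.
#' @param normalized Declare the values as already total-sum scaled.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_in_rows",
                                                 "features_in_rows", "auto"),
                                 normalized = FALSE) {
  orientation <- match.arg(orientation)
  if (orientation == "auto") {
    first <- trimws(strsplit(readLines(path, n = 1L), "\t")[[1]][1])
    orientation <- if (identical(first, "feature_id")) "features_in_rows"
                   else "samples_in_rows"
  }
  m <- read_tsv_matrix(path)
  if (orientation == "features_in_rows") m <- t(m)
  abundance_table(m, normalized = normalized)
}

fmt_real <- function(x) sprintf("%.17g", x)

#' Write an abundance table to a tab-delimited file
#'
#' Values are serialized in full precision so that a read/write round trip is
#' lossless to floating-point resolution.
#'
#' @inheritParams read_abundance_table
#' @param table An [abundance_table()].
#' @export
write_abundance_table <- function(table, path,
                                  orientation = c("samples_in_rows",
                                                  "features_in_rows")) {
  orientation <- match.arg(orientation)
  validate_abundance_table(table)
  v <- table$values
  if (orientation == "features_in_rows") {
    v <- t(v)
    id_col <- "feature_id"
  } else id_col <- "sample_id"
  lines <- c(paste(c(id_col, colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i], fmt_real(v[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# Reserved row identifiers of the weight-matrix file; feature names must not
# collide with them.
WM_RESERVED <- c("intercept", "alpha", "lambda", "cv_spearman", "well_predicted")

#' Construct a trained weight matrix
#'
#' Bundles the per-metabolite elastic net fits: the coefficient matrix W
#' (features x metabolites, on the transformed scales), intercepts, selected
#' hyperparameters, cross-validated Spearman correlations, and the
#' well-predicted flags.
#'
#' @param coefficients Numeric matrix, predictor features in rows, metabolites
#'   in columns, with dimnames set.
#' @param intercepts,alpha,lambda,cv_spearman Numeric vectors, one entry per
#'   metabolite.
#' @param well_predicted Logical vector, one entry per metabolite.  Must be
#'   `TRUE` only where `cv_spearman` meets the training threshold and the
#'   coefficient column is not identically zero.
#' @param threshold The well-predicted threshold the flags were derived with
#'   (stored for reference; default 0.3).
#' @return An object of class `weight_matrix`.
#' @export
weight_matrix <- function(coefficients, intercepts, alpha, lambda,
                          cv_spearman, well_predicted, threshold = 0.3) {
  coefficients <- as.matrix(coefficients)
  m <- ncol(coefficients)
  out <- structure(list(
    coefficients = coefficients,
    intercepts = stats::setNames(as.numeric(intercepts), colnames(coefficients)),
    alpha = stats::setNames(as.numeric(alpha), colnames(coefficients)),
    lambda = stats::setNames(as.numeric(lambda), colnames(coefficients)),
    cv_spearman = stats::setNames(as.numeric(cv_spearman), colnames(coefficients)),
    well_predicted = stats::setNames(as.logical(well_predicted), colnames(coefficients)),
    threshold = threshold
  ), class = "weight_matrix")
  validate_weight_matrix(out)
}

#' Validate a weight matrix
#'
#' @param x A `weight_matrix`.
#' @return `x` invisibly, or an error naming the violated invariant.
#' @export
validate_weight_matrix <- function(x) {
  stopifnot(inherits(x, "weight_matrix"))
  m <- ncol(x$coefficients)
  if (m < 1) stop("no models to serialize: weight matrix has zero metabolites")
  if (is.null(colnames(x$coefficients)) ||
      (nrow(x$coefficients) > 0 && is.null(rownames(x$coefficients))))
    stop("weight matrix requires feature and metabolite identifiers")
  if (anyDuplicated(colnames(x$coefficients)))
    stop("duplicate metabolite identifiers in weight matrix")
  if (anyDuplicated(rownames(x$coefficients)))
    stop("duplicate feature identifiers in weight matrix")
  if (any(rownames(x$coefficients) %in% WM_RESERVED))
    stop("feature identifiers collide with reserved names: ",
         paste(intersect(rownames(x$coefficients), WM_RESERVED), collapse = ", "))
  for (fld in c("intercepts", "alpha", "lambda", "cv_spearman", "well_predicted"))
    if (length(x[[fld]]) != m)
      stop(sprintf("field '%s' has %d entries for %d metabolites", fld,
                   length(x[[fld]]), m))
  if (any(x$alpha < 0 | x$alpha > 1, na.rm = TRUE))
    stop("alpha outside [0, 1]")
  if (any(x$lambda < 0, na.rm = TRUE)) stop("lambda must be >= 0")
  if (any(abs(x$cv_spearman) > 1 + 1e-12, na.rm = TRUE))
    stop("cv_spearman outside [-1, 1]")
  zero_col <- colSums(x$coefficients != 0) == 0
  offenders <- x$well_predicted & zero_col
  if (any(offenders))
    stop("well-predicted metabolite(s) with all-zero coefficient column: ",
         paste(colnames(x$coefficients)[offenders], collapse = ", "))
  x
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("weight_matrix: %d predictor features x %d metabolites (%d well predicted at r >= %g)\n",
              nrow(x$coefficients), ncol(x$coefficients),
              sum(x$well_predicted), x$threshold))
  invisible(x)
}

#' Per-metabolite training summary
#'
#' @param object A `weight_matrix`.
#' @param ... Unused.
#' @return A data frame with one row per metabolite: selected `alpha` and
#'   `lambda`, `cv_spearman`, model size (`n_nonzero`, split into
#'   `n_positive`/`n_negative`), and the `well_predicted` flag.
#' @export
summary.weight_matrix <- function(object, ...) {
  b <- object$coefficients
  data.frame(
    metabolite_id = colnames(b),
    alpha = unname(object$alpha),
    lambda = unname(object$lambda),
    cv_spearman = unname(object$cv_spearman),
    n_nonzero = colSums(b != 0),
    n_positive = colSums(b > 0),
    n_negative = colSums(b < 0),
    well_predicted = unname(object$well_predicted),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Serialize / deserialize a weight matrix
#'
#' The on-disk layout is a TSV whose first five rows are the reserved records
#' `intercept`, `alpha`, `lambda`, `cv_spearman`, `well_predicted` (one column
#' per metabolite), followed by one row per predictor feature carrying the
#' coefficients.  Reals are written in full-precision scientific notation so
#' the round trip is exact to better than 1e-12 relative error.
#'
#' @param model A valid [weight_matrix()].
#' @param path Output/input file path.
#' @return `read_weight_matrix` returns a `weight_matrix`;
#'   `write_weight_matrix` returns `path` invisibly.
#' @export
write_weight_matrix <- function(model, path) {
  validate_weight_matrix(model)
  b <- model$coefficients
  header <- paste(c("id", colnames(b)), collapse = "\t")
  res <- rbind(intercept = model$intercepts, alpha = model$alpha,
               lambda = model$lambda, cv_spearman = model$cv_spearman,
               well_predicted = as.numeric(model$well_predicted))
  body <- rbind(res, b)
  lines <- c(header, vapply(seq_len(nrow(body)), function(i) {
    paste(c(rownames(body)[i], fmt_real(body[i, ])), collapse = "\t")
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  m <- read_tsv_matrix(path)
  missing <- setdiff(WM_RESERVED, rownames(m))
  if (length(missing))
    stop("weight matrix file is missing reserved record(s): ",
         paste(missing, collapse = ", "), " in ", path)
  feats <- setdiff(rownames(m), WM_RESERVED)
  coef <- m[feats, , drop = FALSE]
  weight_matrix(coef,
                intercepts = m["intercept", ],
                alpha = m["alpha", ],
                lambda = m["lambda", ],
                cv_spearman = m["cv_spearman", ],
                well_predicted = m["well_predicted", ] != 0)
}

#' Read gene sets (GMT or two-column long format)
#'
#' GMT lines are `set_name<TAB>description<TAB>member1<TAB>member2...`.  The
#' long format is a headerless two-column TSV of (set_name, member) rows.
#' Duplicate members within a set are removed with a warning; empty sets are
#' an error.
#'
#' @param path Path to the gene-set file.
#' @param format `"auto"` (GMT when the extension is `.gmt`, long otherwise),
#'   `"gmt"`, or `"long"`.
#' @return A named list of character vectors (class `gene_set_collection`),
#'   with set descriptions in the `"descriptions"` attribute when present.
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "long")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "long"
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    names_ <- vapply(parts, `[`, character(1), 1L)
    desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
    sets <- lapply(seq_along(parts), function(i) {
      mem <- parts[[i]][-(1:2)]
      mem <- mem[nzchar(mem)]
      if (!length(mem))
        stop(sprintf("gene set '%s' has no members (line %d of %s)",
                     names_[i], i, path))
      if (anyDuplicated(mem)) {
        warning(sprintf("gene set '%s': duplicate members removed", names_[i]))
        mem <- unique(mem)
      }
      mem
    })
    names(sets) <- names_
    attr(sets, "descriptions") <- stats::setNames(desc, names_)
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, colClasses = "character")
    if (ncol(df) != 2)
      stop("long-format gene-set file must have exactly two columns: ", path)
    if (any(!nzchar(trimws(df[[2]]))))
      stop("gene set with empty member field in ", path)
    sets <- split(df[[2]], factor(df[[1]], levels = unique(df[[1]])))
    sets <- lapply(names(sets), function(nm) {
      mem <- sets[[nm]]
      if (anyDuplicated(mem)) {
        warning(sprintf("gene set '%s': duplicate members removed", nm))
        mem <- unique(mem)
      }
      mem
    })
    names(sets) <- unique(df[[1]])
  }
  if (anyDuplicated(names(sets)))
    stop("duplicate set names in ", path)
  class(sets) <- "gene_set_collection"
  sets
}

#' @param sets A `gene_set_collection` (or named list of character vectors).
#' @rdname read_gene_sets
#' @export
write_gene_sets <- function(sets, path, format = c("gmt", "long")) {
  format <- match.arg(format)
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  desc <- attr(sets, "descriptions")
  if (format == "gmt") {
    lines <- vapply(names(sets), function(nm) {
      d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
      paste(c(nm, d, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
  } else {
    df <- data.frame(set = rep(names(sets), lengths(sets)),
                     member = unlist(sets, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Align two abundance tables on shared samples
#'
#' Paired feature/metabolite tables are matched by sample identifier
#' intersection (order-insensitive: the first table's ordering of the shared
#' samples is used for both outputs).
#'
#' @param x,y `abundance_table`s over overlapping sample sets.
#' @param min_shared Minimum number of shared samples (default 3) below which
#'   alignment is refused.
#' @return A list with elements `x` and `y` restricted to the shared samples.
#' @export
align_samples <- function(x, y, min_shared = 3L) {
  shared <- intersect(sample_ids(x), sample_ids(y))
  if (length(shared) < min_shared)
    stop(sprintf("tables share only %d sample(s); at least %d are required",
                 length(shared), min_shared))
  list(
    x = abundance_table(x$values[shared, , drop = FALSE], normalized = x$normalized),
    y = abundance_table(y$values[shared, , drop = FALSE], normalized = y$normalized)
  )
}
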