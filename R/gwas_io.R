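#' @keywords internal
"_PACKAGE"

# Canonical internal column schema for one GWAS association record.
SSF_COLUMNS <- c(
  variant_id = "variant_id", chromosome = "chromosome",
  position = "base_pair_location", effect_allele = "effect_allele",
  other_allele = "other_allele", eaf = "effect_allele_frequency",
  beta = "beta", se = "standard_error", p = "p_value", n = "n",
  n_case = "n_case", n_control = "n_control"
)
REQUIRED_FIELDS <- c("variant_id", "chromosome", "position", "effect_allele",
                     "other_allele", "beta", "se", "p", "n")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics set
#'
#' Bundles per-variant GWAS association records for one trait and ancestry
#' into a validated container.  `snps` must contain the canonical columns
#' `variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#' `beta`, `se`, `p`, `n`, and optionally `eaf`, `n_case`, `n_control`.
#'
#' @param snps data.frame of association records.
#' @param trait_label trait name (e.g. "TG").
#' @param ancestry_label ancestry label (e.g. "EUR", "EAS"); must be nonempty.
#' @param binary_trait logical; `TRUE` when `beta` is a log odds ratio.
#' @return An object of class `summary_stat_set`.
#' @export
summary_stat_set <- function(snps, trait_label = "trait",
                             ancestry_label = "EUR", binary_trait = FALSE) {
  stopifnot(is.data.frame(snps))
  if (!nzchar(ancestry_label)) stop("ancestry_label must be nonempty")
  for (col in REQUIRED_FIELDS) {
    if (is.null(snps[[col]])) stop("missing required column: ", col)
  }
  if (is.null(snps$eaf)) snps$eaf <- NA_real_
  if (anyDuplicated(snps$variant_id)) {
    stop("variant_id must be unique within a summary_stat_set")
  }
  rownames(snps) <- NULL
  structure(
    list(trait_label = trait_label, ancestry_label = ancestry_label,
         binary_trait = isTRUE(binary_trait), snps = snps),
    class = "summary_stat_set"
  )
}

#' @export
print.summary_stat_set <- function(x, ...) {
  cat(sprintf("summary_stat_set: %s (%s%s), %d variants\n",
              x$trait_label, x$ancestry_label,
              if (x$binary_trait) ", binary" else "", nrow(x$snps)))
  invisible(x)
}

# Row-level validity under the schema invariants; returns a logical vector.
valid_ssf_rows <- function(d) {
  ok <- !is.na(d$variant_id) & nzchar(d$variant_id) &
    !is.na(d$position) & d$position >= 1 &
    d$effect_allele %in% VALID_ALLELES & d$other_allele %in% VALID_ALLELES &
    d$effect_allele != d$other_allele &
    !is.na(d$beta) & is.finite(d$beta) &
    !is.na(d$se) & d$se > 0 &
    !is.na(d$p) & d$p > 0 & d$p <= 1 &
    !is.na(d$n) & d$n > 0
  # eaf is optional; when present it must be a frequency
  ok & (is.na(d$eaf) | (d$eaf > 0 & d$eaf < 1))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a GWAS-SSF-style delimited file into a [summary_stat_set()].
#' Columns with GWAS-SSF names (`variant_id`, `chromosome`,
#' `base_pair_location`, `effect_allele`, `other_allele`,
#' `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, `n`) are
#' recognised natively; any other dialect is adapted through `column_map`.
#' Rows violating the schema (non-ACGT or identical alleles, `se <= 0`,
#' `p` outside (0,1], missing core fields) are dropped with a message.
#' A p-value of exactly 0 (a common underflow in consortium files) is
#' clamped to the smallest positive double with a warning rather than
#' dropped.
#'
#' @param path file path to a delimited text file with a header row.
#' @param column_map optional named character vector mapping canonical field
#'   names (`variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `n`, ...) to the file's
#'   column names.
#' @param binary_trait logical, passed through to the set.
#' @param trait_label,ancestry_label labels for the returned set.
#' @param sep field separator (default tab).
#' @return A `summary_stat_set`.
#' @export
read_summary_stats <- function(path, column_map = NULL, binary_trait = FALSE,
                               trait_label = "trait", ancestry_label = "EUR",
                               sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cmap <- SSF_COLUMNS
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map

  d <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(cmap)) {
    src <- cmap[[field]]
    if (src %in% names(raw)) {
      d[[field]] <- raw[[src]]
    } else if (field %in% REQUIRED_FIELDS) {
      stop("missing required column: ", src)
    } else {
      d[[field]] <- NA
    }
  }
  d$chromosome <- as.character(d$chromosome)
  d$variant_id <- as.character(d$variant_id)
  d$effect_allele <- toupper(as.character(d$effect_allele))
  d$other_allele <- toupper(as.character(d$other_allele))
  for (col in c("position", "eaf", "beta", "se", "p", "n", "n_case",
                "n_control")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }

  zero_p <- !is.na(d$p) & d$p == 0
  if (any(zero_p)) {
    d$p[zero_p] <- .Machine$double.xmin
    warning(sum(zero_p), " p-value(s) of 0 clamped to smallest positive value")
  }

  keep <- valid_ssf_rows(d)
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped during validation (",
            nrow(d), " read)")
  }
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("no valid rows in ", path)
  summary_stat_set(d, trait_label = trait_label,
                   ancestry_label = ancestry_label,
                   binary_trait = binary_trait)
}

#' Write a summary-statistics set as GWAS-SSF-style TSV
#'
#' Inverse of [read_summary_stats()]: writing then reading reproduces the
#' set field-for-field.  Optional columns that are entirely missing (`eaf`,
#' `n_case`, `n_control`) are omitted from the file.
#'
#' @param set a `summary_stat_set`, nonempty.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(set, path) {
  stopifnot(inherits(set, "summary_stat_set"))
  if (nrow(set$snps) == 0L) stop("refusing to write an empty set")
  d <- set$snps
  out <- data.frame(row.names = seq_len(nrow(d)))
  for (field in names(SSF_COLUMNS)) {
    if (field %in% names(d) && !all(is.na(d[[field]]))) {
      out[[SSF_COLUMNS[[field]]]] <- d[[field]]
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD correlation matrix from TSV
#'
#' Expects a square numeric matrix of signed correlations r with variant ids
#' as both header row and first column.  Entries must lie in \[-1, 1\] and
#' the diagonal must be 1; asymmetries up to 1e-8 are silently symmetrized,
#' larger ones are an error.
#'
#' @param path file path.
#' @param tol symmetry / diagonal tolerance.
#' @return A named square matrix of class `ld_matrix`.
#' @export
read_ld_matrix <- function(path, tol = 1e-8) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  r <- as.matrix(raw)
  as_ld_matrix(r, tol = tol)
}

#' Validate a matrix as an LD matrix
#'
#' @param r square numeric matrix with variant ids as dimnames.
#' @param tol symmetry / diagonal tolerance.
#' @return The validated, exactly symmetric matrix with class `ld_matrix`.
#' @export
as_ld_matrix <- function(r, tol = 1e-8) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(rownames(r)) || is.null(colnames(r))) {
    stop("LD matrix needs variant ids as dimnames")
  }
  if (!identical(rownames(r), colnames(r))) {
    stop("LD matrix row and column ids disagree")
  }
  if (any(!is.finite(r)) || any(abs(r) > 1 + tol)) {
    stop("LD entries must be finite correlations in [-1, 1]")
  }
  if (any(abs(diag(r) - 1) > tol)) stop("LD matrix diagonal must be 1")
  if (max(abs(r - t(r))) > tol) stop("LD matrix asymmetric beyond tolerance")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  class(r) <- c("ld_matrix", class(r))
  r
}

#' Write an LD matrix as TSV
#' @param r an `ld_matrix` (or any named square correlation matrix).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(r, path) {
  d <- as.data.frame(unclass(r), check.names = FALSE)
  utils::write.table(cbind(variant_id = rownames(r), d), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
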