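#' Molecule roles and feature views
#'
#' Every descriptor column in a reaction table belongs to exactly one of four
#' molecule roles: the solvent, the chiral phosphoric acid catalyst, the
#' nucleophile, or the imine electrophile. Feature views select role subsets:
#' `"all"` keeps every column, `"exclude_imine"` drops the imine columns
#' (the nucleophile-focused view, useful because imines are hard to isolate
#' and characterise), and `"exclude_nucleophile"` drops the nucleophile
#' columns (the imine-focused view).
#'
#' @name roles-and-views
NULL

.molecule_roles <- c("solvent", "catalyst", "nucleophile", "imine")
.feature_views <- c("all", "exclude_imine", "exclude_nucleophile")

#' Construct a reaction feature table
#'
#' A `reaction_table` holds one row per reaction: a numeric descriptor matrix
#' with named columns, a molecule role for every column, and (optionally) the
#' observed enantioselectivity target \eqn{\Delta\Delta G^\ddag} in kcal/mol.
#'
#' @param features numeric matrix, reactions x descriptors, with unique
#'   column names.
#' @param roles named character vector mapping every feature name to one of
#'   `"solvent"`, `"catalyst"`, `"nucleophile"`, `"imine"`.
#' @param target optional numeric vector of \eqn{\Delta\Delta G^\ddag} values
#'   (kcal/mol), one per reaction; `NULL` for unlabeled data.
#' @param ids optional character vector of reaction identifiers.
#' @param source_label free-text provenance label (e.g. a reaction-type
#'   group name).
#' @return an object of class `reaction_table`.
#' @export
reaction_table <- function(features, roles, target = NULL, ids = NULL,
                           source_label = "") {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  fn <- colnames(features)
  if (is.null(fn) || anyDuplicated(fn))
    stop("feature columns must have unique names", call. = FALSE)
  if (nrow(features) > 0 && any(!is.finite(features)))
    stop("data error: non-finite feature value at row ",
         which(!is.finite(features), arr.ind = TRUE)[1, 1],
         ", column '", fn[which(!is.finite(features), arr.ind = TRUE)[1, 2]],
         "'", call. = FALSE)
  roles <- unlist(roles)
  missing_role <- setdiff(fn, names(roles))
  if (length(missing_role))
    stop("schema error: no role for column '", missing_role[1], "'",
         call. = FALSE)
  roles <- roles[fn]
  bad <- !roles %in% .molecule_roles
  if (any(bad))
    stop("schema error: unknown role '", roles[bad][1], "' for column '",
         fn[bad][1], "'", call. = FALSE)
  if (is.null(ids)) ids <- if (nrow(features)) paste0("rxn_", seq_len(nrow(features))) else character()
  ids <- as.character(ids)
  if (length(ids) != nrow(features))
    stop("ids length must equal the number of reactions", call. = FALSE)
  if (!is.null(target)) {
    target <- as.numeric(target)
    if (length(target) != nrow(features))
      stop("target length must equal the number of reactions", call. = FALSE)
    if (any(!is.finite(target)))
      stop("data error: non-finite target value at row ",
           which(!is.finite(target))[1], call. = FALSE)
  }
  structure(list(ids = ids, features = features,
                 roles = stats::setNames(as.character(roles), fn),
                 target = target, source_label = as.character(source_label)),
            class = "reaction_table")
}

#' @export
print.reaction_table <- function(x, ...) {
  rc <- table(factor(x$roles, levels = .molecule_roles))
  cat("Reaction feature table", if (nzchar(x$source_label))
    paste0(" [", x$source_label, "]"), "\n", sep = "")
  cat("  reactions: ", nrow(x$features), "   features: ", ncol(x$features),
      " (", paste(names(rc), rc, sep = " ", collapse = ", "), ")\n", sep = "")
  cat("  target: ", if (is.null(x$target)) "absent" else
    sprintf("ddG (kcal/mol), range [%.3g, %.3g]",
            min(x$target), max(x$target)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.reaction_table <- function(x) dim(x$features)

#' Subset a reaction table by feature view
#'
#' @param table a [reaction_table].
#' @param view one of `"all"`, `"exclude_imine"`, `"exclude_nucleophile"`.
#' @return a [reaction_table] with the excluded role's columns dropped;
#'   column order and the target are untouched.
#' @export
subset_by_view <- function(table, view = c("all", "exclude_imine",
                                           "exclude_nucleophile")) {
  view <- match.arg(view)
  stopifnot(inherits(table, "reaction_table"))
  if (view == "all") return(table)
  drop_role <- if (view == "exclude_imine") "imine" else "nucleophile"
  keep <- names(table$roles)[table$roles != drop_role]
  reaction_table(table$features[, keep, drop = FALSE], table$roles[keep],
                 target = table$target, ids = table$ids,
                 source_label = table$source_label)
}

#' Subset a reaction table by row
#'
#' @param table a [reaction_table].
#' @param rows integer or logical row index.
#' @return a [reaction_table] with the selected reactions.
#' @export
subset_rows <- function(table, rows) {
  stopifnot(inherits(table, "reaction_table"))
  reaction_table(table$features[rows, , drop = FALSE], table$roles,
                 target = if (is.null(table$target)) NULL else table$target[rows],
                 ids = table$ids[rows], source_label = table$source_label)
}

# full decimal precision so that write -> read is bit-stable
.fmt_num <- function(x) sprintf("%.17g", x)

#' Read a reaction feature table from CSV
#'
#' The data file is a comma-separated table whose first column holds reaction
#' identifiers, whose last column is named `ddg` when the table is labeled,
#' and whose remaining columns are numeric descriptors. The metadata sidecar
#' is a two-column CSV (`feature,role`) assigning a molecule role to every
#' descriptor column.
#'
#' @param data_path path to the feature CSV.
#' @param meta_path path to the role-metadata CSV.
#' @param source_label optional provenance label attached to the result.
#' @return a validated [reaction_table].
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(data_path, meta_path, source_label = "") {
  raw <- utils::read.csv(data_path, check.names = FALSE,
                         colClasses = "character")
  meta <- utils::read.csv(meta_path, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("feature", "role") %in% names(meta)))
    stop("schema error: metadata must have 'feature' and 'role' columns",
         call. = FALSE)
  roles <- stats::setNames(meta$role, meta$feature)
  cn <- names(raw)
  id_col <- cn[1]
  has_target <- "ddg" %in% cn
  feat_cols <- setdiff(cn, c(id_col, "ddg"))
  unmapped <- setdiff(feat_cols, names(roles))
  if (length(unmapped))
    stop("schema error: column '", unmapped[1],
         "' has no role in the metadata file", call. = FALSE)
  to_num <- function(col, nm) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("data error: non-numeric or non-finite value in column '", nm,
           "', row ", bad[1], call. = FALSE)
    v
  }
  n <- nrow(raw)
  feats <- matrix(0, n, length(feat_cols),
                  dimnames = list(NULL, feat_cols))
  for (nm in feat_cols) feats[, nm] <- to_num(raw[[nm]], nm)
  target <- if (has_target && n > 0) to_num(raw[["ddg"]], "ddg")
            else if (has_target) numeric() else NULL
  reaction_table(feats, roles[feat_cols], target = target,
                 ids = raw[[id_col]], source_label = source_label)
}

#' Write a reaction feature table to CSV
#'
#' Values are written with 17 significant digits so a
#' [read_feature_table()] round-trip reproduces the table bit for bit.
#'
#' @param table a [reaction_table].
#' @param data_path path for the feature CSV.
#' @param meta_path path for the role-metadata CSV.
#' @return invisibly, the paths written.
#' @export
write_feature_table <- function(table, data_path, meta_path) {
  stopifnot(inherits(table, "reaction_table"))
  fn <- colnames(table$features)
  cols <- c(list(reaction_id = table$ids),
            lapply(stats::setNames(seq_along(fn), fn),
                   function(j) .fmt_num(table$features[, j])))
  if (!is.null(table$target)) cols$ddg <- .fmt_num(table$target)
  df <- data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, data_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(feature = fn, role = unname(table$roles[fn])),
                   meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(data_path, meta_path))
}
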