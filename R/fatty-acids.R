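#' Built-in fatty-acid definitions
#'
#' Definitions for the 13 fatty acids that dominate salmon muscle lipids
#' (those with mean proportional content above 2% of total FA). Each row
#' carries the carbon chain length, the number of carbon-carbon double bonds,
#' the molecular weight of the corresponding methyl ester (computed from the
#' molecular formula C_{n+1} H_{2(n+1)-2d} O_2), and the saturation class
#' (SFA for 0 double bonds, MUFA for 1, PUFA for 2 or more).
#'
#' @param names optional character vector to subset/reorder the table by FA
#'   name; unknown names raise an error.
#' @return data.frame with columns `name`, `chain_length`, `n_double_bonds`,
#'   `methyl_ester_mw`, `class`.
#' @examples
#' fatty_acid_definitions(c("C20-5 (n-3)", "C22-6 (n-3)"))
#' @export
fatty_acid_definitions <- function(names = NULL) {
  chain <- c(14, 16, 18, 16, 18, 18, 20, 22, 18, 18, 20, 22, 22)
  db    <- c( 0,  0,  0,  1,  1,  1,  1,  1,  2,  3,  5,  5,  6)
  labs  <- c("C14-0", "C16-0", "C18-0", "C16-1 (n-7)", "C18-1 (n-9)",
             "C18-1 (n-7)", "C20-1 (n-9)", "C22-1 (n-11)", "C18-2 (n-6)",
             "C18-3 (n-3)", "C20-5 (n-3)", "C22-5 (n-3)", "C22-6 (n-3)")
  defs <- data.frame(name = labs, chain_length = chain, n_double_bonds = db,
                     methyl_ester_mw = methyl_ester_mw(chain, db),
                     class = ifelse(db == 0, "SFA", ifelse(db == 1, "MUFA", "PUFA")),
                     stringsAsFactors = FALSE)
  if (!is.null(names)) {
    idx <- match(names, defs$name)
    if (anyNA(idx))
      stop("no built-in definition for FA: ",
           paste(names[is.na(idx)], collapse = ", "))
    defs <- defs[idx, , drop = FALSE]
    rownames(defs) <- NULL
  }
  defs
}

#' Molecular weight of a fatty-acid methyl ester
#'
#' For a fatty acid with `chain_length` carbons and `n_double_bonds` C=C
#' bonds, the methyl ester has formula C_{n+1} H_{2(n+1)-2d} O_2.
#'
#' @param chain_length carbons in the fatty-acid chain (including the
#'   carboxyl carbon).
#' @param n_double_bonds number of carbon-carbon double bonds.
#' @return molecular weight in g/mol.
#' @examples
#' methyl_ester_mw(18, 1)  # methyl oleate, 296.49 g/mol
#' @export
methyl_ester_mw <- function(chain_length, n_double_bonds) {
  stopifnot(all(chain_length > 0), all(n_double_bonds >= 0))
  nC <- chain_length + 1
  nH <- 2 * nC - 2 * n_double_bonds
  12.011 * nC + 1.008 * nH + 2 * 15.999
}

#' Validate a definitions table
#' @noRd
check_definitions <- function(defs) {
  needed <- c("name", "n_double_bonds", "methyl_ester_mw")
  if (!all(needed %in% names(defs)))
    stop("definitions must have columns: ", paste(needed, collapse = ", "))
  if (any(defs$n_double_bonds < 0)) stop("n_double_bonds must be >= 0")
  if (any(defs$methyl_ester_mw <= 0)) stop("methyl_ester_mw must be > 0")
  invisible(defs)
}

#' Iodine value of a fatty-acid composition
#'
#' The iodine value (grams of I2 consumed per 100 g fat) is a linear
#' functional of the proportional composition weighted by unsaturation:
#' \deqn{IV = M_w(I_2)\sum_i \#DB(i)\, V_i / M_w(FAMe_i)}
#' with V_i the content of FA i in percent of total FA, #DB(i) its number of
#' C=C double bonds and Mw(FAMe_i) the molecular weight of its methyl ester.
#'
#' @param V named numeric vector (or matrix with FA columns) of proportional
#'   contents in percent of total FA.
#' @param defs definitions table as from [fatty_acid_definitions()]; every FA
#'   name in `V` must resolve.
#' @param mw_iodine molecular weight of I2 in g/mol.
#' @return scalar iodine value (or vector, one per matrix row).
#' @examples
#' iodine_value(c("C18-1 (n-9)" = 100))  # pure methyl oleate: 85.61
#' @export
iodine_value <- function(V, defs = fatty_acid_definitions(), mw_iodine = 253.81) {
  check_definitions(defs)
  if (is.matrix(V) || is.data.frame(V)) {
    V <- as.matrix(V)
    fa <- colnames(V)
  } else {
    fa <- names(V)
    V <- matrix(V, nrow = 1, dimnames = list(NULL, fa))
  }
  if (is.null(fa)) stop("V must carry FA names")
  idx <- match(fa, defs$name)
  if (anyNA(idx))
    stop("missing definition for FA: ", paste(fa[is.na(idx)], collapse = ", "))
  w <- defs$n_double_bonds[idx] / defs$methyl_ester_mw[idx]
  iv <- drop(V %*% w) * mw_iodine
  unname(iv)
}

#' Fatty-acid feature sums
#'
#' Class sums (SFA, MUFA, PUFA) over the modeled FAs, and the sum of EPA
#' (C20-5 n-3) and DHA (C22-6 n-3). If either EPA or DHA is absent from `V`,
#' `EPA_DHA` is reported as `NA` rather than silently zero.
#'
#' @inheritParams iodine_value
#' @return for a vector `V`, a named numeric vector with elements `SFA`,
#'   `MUFA`, `PUFA`, `EPA_DHA`; for a matrix, a matrix with those columns.
#' @examples
#' fa_features(c("C20-5 (n-3)" = 5.1, "C22-6 (n-3)" = 6.8))["EPA_DHA"]
#' @export
fa_features <- function(V, defs = fatty_acid_definitions()) {
  check_definitions(defs)
  vec_in <- !(is.matrix(V) || is.data.frame(V))
  if (vec_in) V <- matrix(V, nrow = 1, dimnames = list(NULL, names(V)))
  V <- as.matrix(V)
  fa <- colnames(V)
  if (is.null(fa)) stop("V must carry FA names")
  idx <- match(fa, defs$name)
  if (anyNA(idx))
    stop("missing definition for FA: ", paste(fa[is.na(idx)], collapse = ", "))
  cls <- defs$class[idx]
  out <- cbind(
    SFA  = rowSums(V[, cls == "SFA", drop = FALSE]),
    MUFA = rowSums(V[, cls == "MUFA", drop = FALSE]),
    PUFA = rowSums(V[, cls == "PUFA", drop = FALSE]))
  epa <- match("C20-5 (n-3)", fa)
  dha <- match("C22-6 (n-3)", fa)
  EPA_DHA <- if (is.na(epa) || is.na(dha)) rep(NA_real_, nrow(V)) else
    V[, epa] + V[, dha]
  out <- cbind(out, EPA_DHA = EPA_DHA)
  if (vec_in) out[1, ] else out
}

#' Convert proportional FA contents to absolute contents
#'
#' Proportional contents are percentages of total FA; absolute contents are
#' percentages of the whole sample. The two are linked through the sample's
#' total fat content: `absolute = V * fat / 100`.
#'
#' @param V proportional contents (% of total FA), vector or sample-by-FA
#'   matrix.
#' @param fat total fat content (% of sample), scalar or one value per row.
#' @return absolute contents (% of sample), same shape as `V`.
#' @export
to_absolute <- function(V, fat) {
  if (any(fat <= 0)) stop("fat content must be > 0")
  if (is.matrix(V) || is.data.frame(V)) as.matrix(V) * (fat / 100) else V * fat / 100
}

#' Convert absolute FA contents back to proportional contents
#'
#' Inverse of [to_absolute()]: `V = absolute * 100 / fat`. Round trip is exact
#' to numerical precision.
#'
#' @param absolute absolute contents (% of sample), vector or matrix.
#' @param fat total fat content (% of sample), scalar or one value per row.
#' @return proportional contents (% of total FA).
#' @export
to_proportional <- function(absolute, fat) {
  if (any(fat <= 0)) {
    if (any(as.matrix(absolute)[fat <= 0, ] != 0))
      stop("fat content is 0 but absolute contents are nonzero")
    stop("fat content must be > 0")
  }
  if (is.matrix(absolute) || is.data.frame(absolute))
    as.matrix(absolute) * (100 / fat) else absolute * 100 / fat
}

#' Write / read composition tables
#'
#' Composition tables are CSV with a `sample_id` column, one column per FA
#' (proportional content, % of total FA) and a final `fat` column (% of
#' sample).
#'
#' @param comps composition object as returned by [draw_compositions()], or
#'   any list with elements `V` (matrix), `fat`, `sample_ids`.
#' @param path CSV path.
#' @return `path` invisibly (write); a composition list (read).
#' @export
write_composition_csv <- function(comps, path) {
  df <- data.frame(sample_id = comps$sample_ids, comps$V, fat = comps$fat,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_composition_csv
#' @export
read_composition_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  fa <- setdiff(names(df), c("sample_id", "fat"))
  list(V = as.matrix(df[, fa, drop = FALSE]), fat = df$fat,
       sample_ids = as.character(df$sample_id), fa_names = fa)
}

#' Write fatty-acid definitions to YAML
#'
#' @param defs definitions data.frame.
#' @param path YAML path.
#' @export
write_definitions_yaml <- function(defs, path) {
  yaml::write_yaml(lapply(seq_len(nrow(defs)), function(i) as.list(defs[i, ])),
                   path)
  invisible(path)
}

#' @rdname write_definitions_yaml
#' @export
read_definitions_yaml <- function(path) {
  rows <- yaml::read_yaml(path)
  defs <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  check_definitions(defs)
  defs
}
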