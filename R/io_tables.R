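#' The fixed RATA attribute list
#'
#' Seventeen scored aroma descriptors used on the whisky panel, plus the
#' unscored free-text option `"other"` which is excluded from all
#' statistics.
#'
#' @return character vector of 17 attribute names (without `"other"`).
#' @export
rata_attributes <- function() {
  c("solvent", "apple", "pear", "flowery", "butter", "fruity", "woody",
    "honey", "melon", "caramel", "peach", "coconut", "clove", "orange",
    "smoky", "phenolic", "vanilla")
}

#' Construct a RATA sensory dataset
#'
#' Rate-all-that-apply records: per panellist and sample, up to 5 checked
#' attributes rated 1 (low) to 3 (high); intensity 0 encodes "not checked"
#' (the CATA negative). Unlisted (panellist, sample, attribute) triples are
#' implicitly 0.
#'
#' @param records data.frame with columns `panellist`, `sample`,
#'   `attribute`, `intensity` (integers 0..3).
#' @param sample_meta data.frame with columns `sample`, `class` (two-level
#'   label, e.g. Scotch/American), `abv` (alcohol by volume, percent; 20,
#'   40 or other).
#' @param attributes scored attribute vocabulary; defaults to
#'   [rata_attributes()]. `"other"` records are carried but never scored.
#' @return object of class `rata_dataset`.
#' @export
rata_dataset <- function(records, sample_meta,
                         attributes = rata_attributes()) {
  need <- c("panellist", "sample", "attribute", "intensity")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "))
  records$panellist <- as.character(records$panellist)
  records$sample <- as.character(records$sample)
  records$attribute <- as.character(records$attribute)
  records$intensity <- as.integer(records$intensity)
  if (any(is.na(records$intensity)) ||
      any(records$intensity < 0L | records$intensity > 3L))
    stop("RATA intensities must lie in 0..3")
  bad_attr <- setdiff(unique(records$attribute), c(attributes, "other"))
  if (length(bad_attr))
    stop("unknown attributes: ", paste(bad_attr, collapse = ", "))
  checked <- records[records$intensity >= 1L & records$attribute != "other", ]
  if (nrow(checked)) {
    k <- table(paste(checked$panellist, checked$sample, sep = "\r"))
    if (any(k > 5L))
      stop("more than 5 checked attributes for a panellist-sample pair: ",
           names(k)[which.max(k)])
  }
  if (!all(c("sample", "class") %in% names(sample_meta)))
    stop("sample_meta needs columns sample, class")
  sample_meta$sample <- as.character(sample_meta$sample)
  missing_meta <- setdiff(unique(records$sample), sample_meta$sample)
  if (length(missing_meta))
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  structure(list(records = records, sample_meta = sample_meta,
                 attributes = attributes),
            class = "rata_dataset")
}

#' @export
print.rata_dataset <- function(x, ...) {
  cat("<rata_dataset> ", length(unique(x$records$panellist)),
      " panellists x ", nrow(x$sample_meta), " samples, ",
      length(x$attributes), " scored attributes, ",
      nrow(x$records), " records\n", sep = "")
  invisible(x)
}

#' Read / write RATA records as CSV
#'
#' Two files: the records CSV (columns panellist, sample, attribute,
#' intensity) and a sample metadata CSV (columns sample, class, abv).
#'
#' @param path records CSV path.
#' @param meta_path sample metadata CSV path.
#' @param attributes scored attribute vocabulary.
#' @return a [rata_dataset()].
#' @export
read_rata <- function(path, meta_path, attributes = rata_attributes()) {
  if (!file.exists(path)) stop("RATA file not found: ", path)
  if (!file.exists(meta_path)) stop("RATA metadata not found: ", meta_path)
  rata_dataset(utils::read.csv(path, stringsAsFactors = FALSE),
               utils::read.csv(meta_path, stringsAsFactors = FALSE),
               attributes = attributes)
}

#' @rdname read_rata
#' @param r a [rata_dataset()].
#' @export
write_rata <- function(r, path, meta_path) {
  stopifnot(inherits(r, "rata_dataset"))
  utils::write.csv(r$records, path, row.names = FALSE)
  utils::write.csv(r$sample_meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' Write / read a compound table as CSV
#'
#' Long format: columns `sample`, `compound`, `rel_area`, plus a `class`
#' column carrying the sample label. Round-trips sample ids, compound names
#' and relative areas (6 significant digits preserved by plain decimal
#' printing).
#'
#' @param tab a `compound_table` (see [build_compound_table()]).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_compound_table <- function(tab, path) {
  stopifnot(inherits(tab, "compound_table"))
  nz <- which(tab$rel_area != 0, arr.ind = TRUE)
  df <- data.frame(sample = tab$samples[nz[, 1]],
                   compound = tab$compounds[nz[, 2]],
                   rel_area = tab$rel_area[nz],
                   class = tab$meta$class[match(tab$samples[nz[, 1]],
                                                tab$meta$sample)])
  df <- df[order(match(df$sample, tab$samples),
                 match(df$compound, tab$compounds)), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compound_table
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop("compound table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "compound", "rel_area")
  if (!all(need %in% names(df)))
    stop("compound table needs columns ", paste(need, collapse = ", "))
  samples <- unique(df$sample)
  compounds <- unique(df$compound)
  X <- matrix(0, length(samples), length(compounds))
  X[cbind(match(df$sample, samples), match(df$compound, compounds))] <-
    df$rel_area
  meta <- unique(data.frame(sample = df$sample,
                            class = if ("class" %in% names(df)) df$class
                                    else NA_character_,
                            stringsAsFactors = FALSE))
  new_compound_table(samples, compounds, X, meta)
}

new_compound_table <- function(samples, compounds, rel_area, meta,
                               internal_standard = NA_character_) {
  stopifnot(nrow(rel_area) == length(samples),
            ncol(rel_area) == length(compounds), all(rel_area >= 0))
  dimnames(rel_area) <- list(samples, compounds)
  structure(list(samples = samples, compounds = compounds,
                 rel_area = rel_area, meta = meta,
                 internal_standard = internal_standard),
            class = "compound_table")
}

#' @export
print.compound_table <- function(x, ...) {
  cat("<compound_table> ", length(x$samples), " samples x ",
      length(x$compounds), " compounds",
      if (!is.na(x$internal_standard))
        paste0(", normalized to ", x$internal_standard), "\n", sep = "")
  invisible(x)
}

#' Binary (qualitative) variant of a compound table
#'
#' All nonzero relative areas become 1: the detected / not-detected matrix
#' used for the qualitative classification variant.
#'
#' @param tab a `compound_table`.
#' @return a `compound_table` whose `rel_area` contains only 0 and 1.
#' @export
binary_compound_table <- function(tab) {
  stopifnot(inherits(tab, "compound_table"))
  tab$rel_area <- (tab$rel_area > 0) * 1
  tab$internal_standard <- NA_character_
  tab
}
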