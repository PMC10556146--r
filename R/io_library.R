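#' Create a spectral library entry
#'
#' @param name compound name.
#' @param ri linear retention index (> 0); required, because identity
#'   scoring combines spectral and RI evidence.
#' @param spectrum a [mass_spectrum()].
#' @param cas CAS registry number (optional).
#' @param odor_quality free-text odor descriptor (optional).
#' @param whisky_typical logical flag (optional).
#' @return object of class `library_entry`.
#' @export
library_entry <- function(name, ri, spectrum, cas = NA_character_,
                          odor_quality = NA_character_,
                          whisky_typical = NA) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("entry needs a nonempty name")
  ri <- as.numeric(ri)
  if (length(ri) != 1L || !is.finite(ri) || ri <= 0)
    stop("entry '", name, "' needs a positive retention index")
  if (!is_mass_spectrum(spectrum))
    stop("entry '", name, "' needs a mass_spectrum")
  structure(list(name = name, cas = as.character(cas), ri = ri,
                 spectrum = spectrum,
                 odor_quality = as.character(odor_quality),
                 whisky_typical = whisky_typical),
            class = "library_entry")
}

#' @export
print.library_entry <- function(x, ...) {
  cat("<library_entry> ", x$name, " (RI ", format(x$ri), ", ",
      length(x$spectrum$mz), " peaks)\n", sep = "")
  invisible(x)
}

#' Read an MSP-style spectral library
#'
#' Records are blank-line separated blocks of `Key: value` header lines
#' (Name, CAS, RI; case-insensitive; `Synon`, `Comment` etc. ignored)
#' followed by whitespace-separated `m/z intensity` pairs, one or more pairs
#' per line. `Num Peaks:` is honoured when present but not required.
#' Records without an RI are rejected: the combined identification score is
#' undefined without one. Duplicate names are allowed (isomers, stereoisomer
#' pairs) and reported via a message.
#'
#' @param path file path.
#' @return list of [library_entry()] objects in file order.
#' @export
read_msp_library <- function(path) {
  if (!file.exists(path))
    stop("library file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  blocks <- lapply(blocks, function(b) b[nzchar(trimws(b))])
  blocks <- blocks[lengths(blocks) > 0]
  entries <- lapply(blocks, parse_msp_block)
  nm <- vapply(entries, function(e) e$name, character(1))
  if (anyDuplicated(nm))
    message("duplicate library names: ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  unname(entries)
}

parse_msp_block <- function(b) {
  hdr <- grepl("^[A-Za-z][A-Za-z0-9 _/-]*:", b)
  keys <- tolower(trimws(sub(":.*$", "", b[hdr])))
  vals <- trimws(sub("^[^:]*:", "", b[hdr]))
  name <- vals[match("name", keys)]
  if (is.na(name)) stop("MSP record without a Name field")
  ri_raw <- vals[match(c("ri", "retentionindex", "retention_index"), keys)]
  ri_raw <- ri_raw[!is.na(ri_raw)][1]
  if (is.na(ri_raw))
    stop("MSP record '", name, "' lacks an RI field")
  cas <- vals[match(c("cas", "casno", "cas#"), keys)]
  cas <- cas[!is.na(cas)][1]
  odor <- vals[match(c("odor", "odor_quality"), keys)]
  odor <- odor[!is.na(odor)][1]
  peak_tokens <- unlist(strsplit(trimws(b[!hdr]), "[,;[:space:]]+"))
  peak_tokens <- peak_tokens[nzchar(peak_tokens)]
  if (length(peak_tokens) == 0L || length(peak_tokens) %% 2L != 0L)
    stop("MSP record '", name, "' has no valid spectrum peaks")
  num <- suppressWarnings(as.numeric(peak_tokens))
  if (any(is.na(num)))
    stop("MSP record '", name, "' has non-numeric spectrum data")
  mz <- num[seq(1, length(num), 2)]
  int <- num[seq(2, length(num), 2)]
  library_entry(name, as.numeric(ri_raw),
                mass_spectrum(mz, int), cas = cas, odor_quality = odor)
}

#' Write a spectral library in MSP-style text
#'
#' @param lib list of [library_entry()] objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_msp_library <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in lib) {
    stopifnot(inherits(e, "library_entry"))
    writeLines(paste0("Name: ", e$name), con)
    if (!is.na(e$cas)) writeLines(paste0("CAS: ", e$cas), con)
    writeLines(paste0("RI: ", format(e$ri, digits = 10)), con)
    if (length(e$odor_quality) == 1 && !is.na(e$odor_quality))
      writeLines(paste0("Odor: ", e$odor_quality), con)
    writeLines(paste0("Num Peaks: ", length(e$spectrum$mz)), con)
    writeLines(paste(e$spectrum$mz, format(e$spectrum$intensity, digits = 10),
                     collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
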