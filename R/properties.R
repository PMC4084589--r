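#' Mean and dispersion of a physicochemical property
#'
#' Computes the normalization factors used by the autocovariance descriptor:
#' the mean over the 20 amino acids and, by default, the *mean squared
#' deviation* (the printed normalization, which is a variance). Set
#' `sd = TRUE` for the square-rooted (standard-deviation) variant.
#'
#' @param d a [PhysicochemicalProperty-class].
#' @param sd if `TRUE`, return the square root of the mean squared deviation.
#' @return Named numeric vector `c(mu = ..., sigma = ...)`.
#' @examples
#' p <- PhysicochemicalProperty("TOY", 1:20)
#' propertyStats(p)  # mu 10.5, sigma 33.25
#' @export
propertyStats <- function(d, sd = FALSE) {
  stopifnot(is(d, "PhysicochemicalProperty"))
  v <- d@values
  mu <- mean(v)
  sigma <- mean((v - mu)^2)
  if (sd) sigma <- sqrt(sigma)
  c(mu = mu, sigma = sigma)
}

# Entries whose 20 values all lie in {0, 1} are indicator scales, not
# quantitative properties, and are excluded from every property table.
isIndicatorProperty <- function(values) all(values %in% c(0, 1))

#' Read a physicochemical property table in AAindex format
#'
#' Parses the AAindex1 flat-file dialect: entries delimited by `//`, with an
#' `H` accession line and an `I` line followed by two rows of 10 numeric
#' values in the order A R N D C Q E G H I / L K M F P S T W Y V. Values are
#' reordered to [aaAlphabet()]. Entries whose 20 values are all 0 or 1 are
#' excluded, as are entries with missing (`NA`) values (with a warning).
#'
#' @param path path to an AAindex-format text file.
#' @return List of [PhysicochemicalProperty-class] objects.
#' @seealso [aaindexProperties()] for the full built-in table.
#' @export
readAAIndex <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    warning("empty AAindex file: ", path)
    return(list())
  }
  # split into entries on '//'
  breaks <- cumsum(c(TRUE, grepl("^//", utils::head(lines, -1))))
  entries <- split(lines, breaks)
  aaOrder <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  out <- list()
  for (entry in entries) {
    entry <- entry[!grepl("^//", entry)]
    if (!any(nzchar(trimws(entry)))) next
    hline <- grep("^H ", entry, value = TRUE)
    acc <- if (length(hline)) trimws(sub("^H ", "", hline[1])) else "<unknown>"
    ipos <- grep("^I ", entry)
    if (!length(ipos)) stop("malformed AAindex entry '", acc, "': no I line")
    if (length(entry) < ipos + 2L)
      stop("malformed AAindex entry '", acc, "': truncated value block")
    valueLines <- entry[(ipos + 1L):(ipos + 2L)]
    tokens <- unlist(strsplit(trimws(valueLines), "[[:space:]]+"))
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) != 20L)
      stop("malformed AAindex entry '", acc, "': expected 20 values, got ",
           length(tokens))
    vals <- suppressWarnings(as.numeric(tokens))
    if (any(is.na(vals))) {
      warning("AAindex entry '", acc, "' has missing values; rejected")
      next
    }
    names(vals) <- aaOrder
    if (isIndicatorProperty(vals)) next
    out[[length(out) + 1L]] <- PhysicochemicalProperty(acc, vals[aaAlphabet()])
  }
  out
}

#' Write properties in AAindex format
#'
#' Inverse of [readAAIndex()]; used to generate plain-text fixtures.
#'
#' @param properties list of [PhysicochemicalProperty-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAAIndex <- function(properties, path) {
  aaOrder <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  con <- file(path, "w")
  on.exit(close(con))
  for (p in properties) {
    v <- propertyValues(p)[aaOrder]
    writeLines(c(
      paste("H", propertyId(p)),
      "D synthetic or exported property entry",
      paste("I", "A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V"),
      paste0("  ", paste(formatC(v[1:10], format = "g", digits = 7), collapse = "  ")),
      paste0("  ", paste(formatC(v[11:20], format = "g", digits = 7), collapse = "  ")),
      "//"), con)
  }
  invisible(path)
}

#' The built-in AAindex property table
#'
#' Converts the 544-entry amino-acid index table shipped with the seqinr
#' package into [PhysicochemicalProperty-class] objects, dropping entries
#' with missing values and indicator entries whose 20 values are all 0 or 1.
#'
#' @return List of [PhysicochemicalProperty-class] objects.
#' @examples
#' props <- aaindexProperties()
#' length(props)
#' @export
aaindexProperties <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  raw <- get("aaindex", envir = env)
  out <- list()
  for (e in raw) {
    vals <- e$I
    if (any(is.na(vals))) next
    one <- AA_THREE_TO_ONE[names(vals)]
    names(vals) <- one
    vals <- vals[aaAlphabet()]
    if (isIndicatorProperty(vals)) next
    out[[length(out) + 1L]] <- PhysicochemicalProperty(e$H, vals)
  }
  out
}

#' Seeded random selection of properties
#'
#' Draws `k` distinct properties from a table; the same seed always yields
#' the same selection.
#'
#' @param table list of [PhysicochemicalProperty-class] objects.
#' @param k number of properties to select.
#' @param seed integer seed.
#' @return List of `k` [PhysicochemicalProperty-class] objects.
#' @export
selectRandomProperties <- function(table, k, seed) {
  if (k > length(table))
    stop("cannot select ", k, " properties from a table of ", length(table))
  idx <- withSeed(seed, sample.int(length(table), k))
  table[idx]
}
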