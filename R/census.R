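#' Default census column schema
#'
#' Census exports vary in their column names; the schema maps the canonical
#' field names used by this package onto the columns of a particular file.
#'
#' @param ... Named overrides, e.g. `x = "gx", y = "gy"`.
#' @return A named character vector mapping field name to column name.
#' @export
census_schema <- function(...) {
  schema <- c(tag = "tag", species = "species", x = "x", y = "y",
              dbh = "dbh", status = "status", resprout = "resprout",
              census = "census", date = "date")
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(schema))
    if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    schema[names(dots)] <- dots
  }
  schema
}

# read a delimited file, sniffing tab vs comma from the header line
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a stem census table
#'
#' Reads a delimited (tab or comma) census file with one row per stem record:
#' tag, species, coordinates (m), dbh (cm), vital status, resprout flag,
#' census id and census date (decimal years). Unknown columns are ignored.
#'
#' @param path Path to the file.
#' @param schema Column map from [census_schema()].
#' @return A data frame with the canonical columns `tag`, `species`, `x`, `y`,
#'   `dbh`, `status`, `resprout`, `census`, `date`. `status` is `"alive"` or
#'   `"dead"`; `resprout` is logical.
#' @seealso [write_census()]
#' @export
read_census <- function(path, schema = census_schema()) {
  raw <- read_delimited(path)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols))
    stop("census file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    tag = as.character(raw[[schema["tag"]]]),
    species = as.character(raw[[schema["species"]]]),
    stringsAsFactors = FALSE
  )
  for (f in c("x", "y", "dbh", "date")) {
    v <- raw[[schema[f]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                   schema[f], bad[1], v[bad[1]]))
    out[[f]] <- num
  }
  cens <- suppressWarnings(as.integer(raw[[schema["census"]]]))
  bad <- which(is.na(cens))
  if (length(bad) && nrow(raw))
    stop(sprintf("non-integer census id at data row %d", bad[1]))
  out$census <- cens
  out$status <- as.character(raw[[schema["status"]]])
  rs <- raw[[schema["resprout"]]]
  out$resprout <- if (is.logical(rs)) rs else
    as.logical(rs %in% c("TRUE", "true", "T", "1", 1))
  if (nrow(out)) {
    if (any(out$dbh <= 0, na.rm = TRUE)) {
      i <- which(out$dbh <= 0)[1]
      stop(sprintf("invalid dbh (%g <= 0) at data row %d", out$dbh[i], i))
    }
    if (!all(out$status %in% c("alive", "dead")))
      stop("status must be 'alive' or 'dead'")
  }
  out[, c("tag", "species", "x", "y", "dbh", "status", "resprout",
          "census", "date")]
}

#' Write a stem census table
#'
#' Inverse of [read_census()]: writes the canonical columns as tab-delimited
#' text so that read-then-write round-trips records exactly.
#'
#' @param stems Census data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(stems, path) {
  write.table(stems, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reproductive-status table
#'
#' Maps stem tags of a dioecious family onto sexes (`M`/`F`), as determined
#' from repeat flowering/fruiting surveys.
#'
#' @param path Delimited file with columns `tag` and `sex`.
#' @return Data frame with character `tag` and `sex`.
#' @export
read_repro_table <- function(path) {
  raw <- read_delimited(path)
  if (!all(c("tag", "sex") %in% names(raw)))
    stop("reproductive-status file must have columns 'tag' and 'sex'")
  out <- data.frame(tag = as.character(raw$tag), sex = as.character(raw$sex),
                    stringsAsFactors = FALSE)
  if (nrow(out) && !all(out$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  out
}

#' Classify focal trees
#'
#' Splits the stems passed in into the four focal classes used throughout the
#' analyses: mature palms (dbh >= 15 cm, the size at which *Iriartea* begins
#' fruiting), immature large palms (10 <= dbh < 15 cm, non-fruiting but with
#' full-sized fronds), and female/male trees of a dioecious family as recorded
#' in a reproductive-status table. Palms below 10 cm dbh belong to neither
#' palm class. Callers normally pass the living stems of one census.
#'
#' @param stems Census data frame (one census).
#' @param palm_species Character vector of arborescent palm species codes.
#' @param repro_table Optional data frame from [read_repro_table()]; every tag
#'   in it must occur in `stems`.
#' @param mature_dbh,immature_dbh Class boundaries in cm (defaults 15 and 10).
#' @return An object of class `focal_classes`: a list with data-frame members
#'   `mature_palm`, `immature_palm`, `female`, `male` (the latter two empty
#'   without `repro_table`).
#' @examples
#' stems <- data.frame(tag = c("a", "b", "c"), species = "IRDE",
#'                     x = 1:3, y = 1:3, dbh = c(16, 12, 9),
#'                     status = "alive", resprout = FALSE,
#'                     census = 0L, date = 1996)
#' f <- classify_focals(stems, palm_species = "IRDE")
#' nrow(f$mature_palm); nrow(f$immature_palm)
#' @export
classify_focals <- function(stems, palm_species, repro_table = NULL,
                            mature_dbh = 15, immature_dbh = 10) {
  is_palm <- stems$species %in% palm_species
  mature <- stems[is_palm & stems$dbh >= mature_dbh, , drop = FALSE]
  immature <- stems[is_palm & stems$dbh >= immature_dbh &
                      stems$dbh < mature_dbh, , drop = FALSE]
  female <- male <- stems[0, , drop = FALSE]
  if (!is.null(repro_table) && nrow(repro_table)) {
    missing_tags <- setdiff(repro_table$tag, stems$tag)
    if (length(missing_tags))
      stop("reproductive-status tag(s) not found in census: ",
           paste(utils::head(missing_tags, 5), collapse = ", "))
    idx <- match(repro_table$tag, stems$tag)
    female <- stems[idx[repro_table$sex == "F"], , drop = FALSE]
    male <- stems[idx[repro_table$sex == "M"], , drop = FALSE]
  }
  structure(list(mature_palm = mature, immature_palm = immature,
                 female = female, male = male),
            class = "focal_classes")
}

#' @export
print.focal_classes <- function(x, ...) {
  cat("Focal tree classes:\n")
  for (nm in names(x))
    cat(sprintf("  %-14s %d stems\n", nm, nrow(x[[nm]])))
  invisible(x)
}
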