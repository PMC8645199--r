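#' Read landmark configurations from a TPS file
#'
#' Supports the classic TPS layout: one `LM=<k>` (2-D) or `LM3=<k>` (3-D)
#' record per specimen followed by k coordinate rows, an `ID=` key per
#' specimen, and optional `SCALE=`/`IMAGE=` lines (ignored). All specimens
#' in a file must share landmark count and dimensionality.
#'
#' @param file Path to the TPS file.
#' @param species_map Optional data frame with columns `specimen_id` and
#'   `species_id`; when omitted, species are taken as the part of the
#'   specimen id before the last underscore.
#' @param structure Structure label for the resulting [landmark_set()].
#' @return A `landmark_set`.
#' @export
read_tps <- function(file, species_map = NULL, structure = "structure") {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3?=", lines)
  if (!length(starts)) stop("no LM=/LM3= records found in ", file)
  configs <- list(); ids <- character(0)
  ends <- c(starts[-1] - 1L, length(lines))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    dims <- if (grepl("^LM3=", block[1])) 3L else 2L
    k <- as.integer(sub("^LM3?=", "", block[1]))
    coord_lines <- block[2:(1 + k)]
    m <- t(vapply(strsplit(coord_lines, "[ \t]+"),
                  function(v) as.numeric(v), numeric(dims)))
    if (anyNA(m)) stop("malformed coordinate row in record ", b, " of ", file)
    id_line <- grep("^ID=", block, value = TRUE)
    id <- if (length(id_line)) sub("^ID=", "", id_line[1]) else paste0("specimen_", b)
    configs[[b]] <- m
    ids[b] <- id
  }
  if (is.null(species_map)) {
    species <- sub("_[^_]*$", "", ids)
  } else {
    species <- species_map$species_id[match(ids, species_map$specimen_id)]
    if (anyNA(species)) {
      stop("specimens missing from species_map: ",
           paste(ids[is.na(species)], collapse = ", "))
    }
  }
  landmark_set(configs, ids, species, structure = structure)
}

#' Write a landmark dataset to a TPS file
#'
#' @param lms A [landmark_set()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_tps <- function(lms, file) {
  stopifnot(inherits(lms, "landmark_set"))
  d <- dim(lms$coords)
  tag <- if (d[2] == 3) "LM3=" else "LM="
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(d[3])) {
    writeLines(paste0(tag, d[1]), con)
    writeLines(apply(format(lms$coords[, , i], digits = 12, trim = TRUE),
                     1, paste, collapse = " "), con)
    writeLines(paste0("ID=", lms$specimens$specimen_id[i]), con)
  }
  invisible(file)
}

#' Read landmark configurations from a long-format CSV
#'
#' Expected columns: `specimen_id`, `species_id`, `landmark_index`, `x`,
#' `y`, and optionally `z`. Every specimen must have the same complete set
#' of landmark indices.
#'
#' @param file Path to the CSV file.
#' @param structure Structure label.
#' @return A `landmark_set`.
#' @export
read_landmarks_csv <- function(file, structure = "structure") {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species_id", "landmark_index", "x", "y")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "), " [, z]")
  }
  dims <- if ("z" %in% names(df)) 3L else 2L
  ids <- unique(df$specimen_id)
  ks <- sort(unique(df$landmark_index))
  if (!identical(ks, seq_along(ks))) stop("landmark_index must be 1..K")
  configs <- vector("list", length(ids))
  species <- character(length(ids))
  for (i in seq_along(ids)) {
    sub <- df[df$specimen_id == ids[i], ]
    sub <- sub[order(sub$landmark_index), ]
    if (!identical(sub$landmark_index, ks)) {
      stop("specimen ", ids[i], " is missing landmarks")
    }
    configs[[i]] <- as.matrix(sub[, c("x", "y", if (dims == 3) "z")])
    species[i] <- sub$species_id[1]
  }
  landmark_set(configs, ids, species, structure = structure)
}

#' Write a landmark dataset to long-format CSV
#'
#' @param lms A [landmark_set()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_landmarks_csv <- function(lms, file) {
  stopifnot(inherits(lms, "landmark_set"))
  d <- dim(lms$coords)
  rows <- do.call(rbind, lapply(seq_len(d[3]), function(i) {
    row <- data.frame(specimen_id = lms$specimens$specimen_id[i],
                      species_id = lms$specimens$species_id[i],
                      landmark_index = seq_len(d[1]),
                      x = lms$coords[, 1, i],
                      y = lms$coords[, 2, i])
    if (d[2] == 3) row$z <- lms$coords[, 3, i]
    row
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
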