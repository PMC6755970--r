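#' Write a plate's raw luminescence as CSV
#'
#' Standard 8 x 12 layout: first column holds row labels A-H, header row
#' the column numbers 1-12.
#'
#' @param plate A [plate_grid()] (its `values` are written).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  stopifnot(inherits(plate, "plate_grid"))
  df <- data.frame(row = LETTERS[1:8], plate$values)
  names(df) <- c("row", as.character(1:12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate luminescence CSV
#'
#' Inverse of [write_plate_csv()]; the role/probe annotation comes from
#' a plate map (see [read_plate_map()]).
#'
#' @param path CSV path (row labels A-H in the first column, columns
#'   1-12 in the header).
#' @return 8 x 12 numeric matrix.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(as.character(df[[1L]]), LETTERS[1:8]))
    stop("plate CSV must have row labels A-H in the first column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (ncol(m) != 12L) stop("plate CSV must have 12 data columns")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Write a plate map as TSV
#'
#' One row per well: `plate_id`, `well` (e.g. `A01`), `role`,
#' `probe_id` (empty for non-library wells).
#'
#' @param plates List of [plate_grid()] objects (or one).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(plates, path) {
  if (inherits(plates, "plate_grid")) plates <- list(plates)
  wells <- well_names()
  rows <- do.call(rbind, lapply(plates, function(p)
    data.frame(plate_id = p$plate_id, well = as.vector(wells),
               role = as.vector(p$roles),
               probe_id = ifelse(is.na(as.vector(p$probe_ids)), "",
                                 as.vector(p$probe_ids)),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a plate map TSV
#'
#' @param path TSV with columns `plate_id`, `well`, `role`, `probe_id`.
#' @return data.frame; empty `probe_id` becomes `NA`.
#' @export
read_plate_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("plate_id", "well", "role", "probe_id")
  if (!all(need %in% names(df)))
    stop("plate map needs columns: ", paste(need, collapse = ", "))
  df$probe_id[df$probe_id == ""] <- NA_character_
  df
}

#' Assemble plate_grid objects from a values CSV and a plate map
#'
#' @param csv_path Plate CSV (see [read_plate_csv()]).
#' @param map Plate-map data.frame ([read_plate_map()]) or TSV path.
#' @param plate_id Which plate of the map this CSV holds.
#' @param cell_line,replicate Plate annotations.
#' @return A [plate_grid()].
#' @export
load_plate <- function(csv_path, map, plate_id, cell_line, replicate = 1L) {
  if (is.character(map)) map <- read_plate_map(map)
  m <- map[map$plate_id == plate_id, , drop = FALSE]
  if (nrow(m) != 96L) stop("plate map must describe 96 wells of ", plate_id)
  wells <- well_names()
  idx <- match(as.vector(wells), m$well)
  if (anyNA(idx)) stop("plate map wells must cover A01..H12")
  roles <- matrix(m$role[idx], 8L, 12L)
  ids <- matrix(m$probe_id[idx], 8L, 12L)
  plate_grid(read_plate_csv(csv_path), roles, ids, plate_id, cell_line,
             replicate)
}

#' Write seed sites as BED-like TSV plus 1-based coordinates
#'
#' Writes `utr_id`, `bed_start` (0-based half-open), `end`, `name`
#' (`mir|type`), `score` (type rank 1-4), `strand` (+), alongside the
#' 1-based inclusive `start` used in prose.
#'
#' @param sites Site data.frame from [find_seed_sites()]/[scan_utrs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  out <- data.frame(
    utr_id = sites$utr_id,
    bed_start = sites$start - 1L,
    end = sites$end,
    name = paste(sites$mir_name, sites$site_type, sep = "|"),
    score = unname(SITE_RANK[sites$site_type]),
    strand = "+",
    start_1based = sites$start,
    target_seq = sites$target_seq,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write/read tidy Ct tables
#'
#' @param records Ct data.frame (`sample`, `gene`, `ct`, `role`).
#' @param path TSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_ct_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Load a simulation configuration from JSON or YAML
#'
#' The file holds the arguments of one of the `*_sim_config()`
#' constructors; `type` selects which (`"screen"`, `"utr"` or
#' `"qpcr"`), or is read from a `type` field in the file.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @param type Config type; `NULL` to read it from the file.
#' @return The validated config object.
#' @export
read_sim_config <- function(path, type = NULL) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(type)) type <- lst$type
  lst$type <- NULL
  if (is.null(type)) stop("config type missing (screen/utr/qpcr)")
  if (!is.null(lst$planted_sites))
    lst$planted_sites <- as.data.frame(lst$planted_sites,
                                       stringsAsFactors = FALSE)
  if (!is.null(lst$true_fold))
    lst$true_fold <- as.data.frame(lst$true_fold, stringsAsFactors = FALSE)
  ctor <- switch(match.arg(type, c("screen", "utr", "qpcr")),
                 screen = screen_sim_config,
                 utr = utr_sim_config,
                 qpcr = qpcr_sim_config)
  do.call(ctor, lst)
}
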