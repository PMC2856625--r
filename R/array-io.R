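#' Read a GenePix-Results-style spot table
#'
#' Parses the tab-delimited dialect exported per array by two-channel scanner
#' software: optional `key=value` metadata lines, then a header naming at
#' least Block, Column, Row, Name, F635 Median, F532 Median and Flags
#' (underscore spellings such as `F635_Median` are accepted; unrecognized
#' columns are ignored). Parsing never filters: flagged spots are retained
#' with their flag code so that QC decisions happen downstream.
#'
#' @param path Path to a tab-delimited file.
#' @param layout Optional [array_layout()]; when supplied, each spot label is
#'   resolved against it and unknown labels are retained with `mapped = FALSE`.
#' @return A spot tibble (one row per printed spot) with columns `block`,
#'   `column`, `row`, `name`, `replicate_index` (assigned by order of
#'   appearance per label), `red_median`, `green_median`, `flag`, the
#'   metadata columns `slide_id`, `array_position`, `serum_id` (`NA` for mock
#'   arrays), `day`, `dilution`, and (with a layout) `mapped`.
#' @export
read_gpr <- function(path, layout = NULL) {
  lines <- readLines(path, warn = FALSE)
  norm <- function(x) gsub("_", " ", x, fixed = TRUE)
  is_header <- vapply(lines, function(l) {
    f <- norm(strsplit(l, "\t", fixed = TRUE)[[1]])
    all(c("Block", "Column", "Row", "Name") %in% f)
  }, logical(1), USE.NAMES = FALSE)
  if (!any(is_header)) {
    # no header at all: report the first mandatory column as missing
    stop("GPR format error: missing column 'Block' (no header line found)",
         call. = FALSE)
  }
  h <- which(is_header)[1]
  meta_lines <- lines[seq_len(h - 1)]
  meta_lines <- meta_lines[grepl("=", meta_lines, fixed = TRUE)]
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(ml, "=", fixed = TRUE)[[1]]
    meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }

  fields <- norm(strsplit(lines[h], "\t", fixed = TRUE)[[1]])
  required <- c("Block", "Column", "Row", "Name", "F635 Median", "F532 Median",
                "Flags")
  missing_col <- setdiff(required, fields)
  if (length(missing_col)) {
    stop("GPR format error: missing column '", missing_col[1], "'",
         call. = FALSE)
  }

  body <- lines[-seq_len(h)]
  body <- body[nzchar(body)]
  if (length(body)) {
    cells <- strsplit(body, "\t", fixed = TRUE)
    grab <- function(col, as) {
      i <- match(col, fields)
      as(vapply(cells, function(r) if (length(r) >= i) r[i] else NA_character_,
                character(1)))
    }
    spots <- tibble::tibble(
      block = grab("Block", as.integer),
      column = grab("Column", as.integer),
      row = grab("Row", as.integer),
      name = grab("Name", as.character),
      red_median = grab("F635 Median", as.numeric),
      green_median = grab("F532 Median", as.numeric),
      flag = grab("Flags", as.integer)
    )
  } else {
    spots <- tibble::tibble(
      block = integer(), column = integer(), row = integer(),
      name = character(), red_median = double(), green_median = double(),
      flag = integer()
    )
  }
  if (anyDuplicated(spots[c("block", "column", "row")])) {
    stop("GPR validation error: duplicate grid position (block, column, row)",
         call. = FALSE)
  }
  if (any(spots$red_median < 0, na.rm = TRUE) ||
      any(spots$green_median < 0, na.rm = TRUE)) {
    stop("GPR validation error: negative median intensity", call. = FALSE)
  }
  spots <- spots |>
    dplyr::group_by(.data$name) |>
    dplyr::mutate(replicate_index = dplyr::row_number()) |>
    dplyr::ungroup()

  meta_chr <- function(key, default = NA_character_) {
    if (!is.null(meta[[key]])) meta[[key]] else default
  }
  serum <- meta_chr("serum_id")
  if (!is.na(serum) && identical(toupper(serum), "MOCK")) serum <- NA_character_
  spots <- spots |>
    dplyr::mutate(
      slide_id = meta_chr("slide_id"),
      array_position = as.integer(meta_chr("array_position")),
      serum_id = serum,
      day = as.integer(meta_chr("day")),
      dilution = as.numeric(meta_chr("dilution"))
    )
  if (!is.null(layout)) {
    spots$mapped <- !is.na(layout_label_type(spots$name, layout))
  }
  spots |>
    dplyr::select("block", "column", "row", "name", "replicate_index",
                  "red_median", "green_median", "flag",
                  dplyr::everything())
}

#' Write a spot table in the GPR dialect
#'
#' Inverse of [read_gpr()]: metadata `key=value` lines, a tab-delimited
#' header, one row per spot. Numeric intensities are formatted with 17
#' significant digits so a write/read round trip reproduces every field
#' exactly, and output is byte-deterministic.
#'
#' @param spots A spot tibble as returned by [read_gpr()] or the simulators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gpr <- function(spots, path) {
  meta_cols <- c("slide_id", "array_position", "serum_id", "day", "dilution")
  fmt <- function(x) {
    ifelse(is.na(x), "", sprintf("%.17g", x))
  }
  meta <- character()
  for (mc in meta_cols) {
    if (!mc %in% names(spots)) next
    v <- unique(spots[[mc]])
    if (length(v) > 1) {
      stop("`spots` mixes several arrays (column '", mc,
           "' is not constant); write one array per file", call. = FALSE)
    }
    val <- if (length(v) == 0 || is.na(v)) {
      if (mc == "serum_id") "MOCK" else NA_character_
    } else if (is.numeric(v) && !is.integer(v)) sprintf("%.17g", v)
    else as.character(v)
    if (!is.na(val)) meta <- c(meta, paste0(mc, "=", val))
  }
  header <- paste(c("Block", "Column", "Row", "Name", "ID", "F635 Median",
                    "F532 Median", "Flags"), collapse = "\t")
  rows <- if (nrow(spots)) {
    paste(spots$block, spots$column, spots$row, spots$name, spots$name,
          fmt(spots$red_median), fmt(spots$green_median), spots$flag,
          sep = "\t")
  } else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, header, rows), con, sep = "\n")
  invisible(path)
}

#' Check a scanned array against its print layout
#'
#' Report-only validation: compares observed replicate counts per label with
#' the layout's expectation, and lists unmapped labels and duplicated grid
#' positions. Never errors.
#'
#' @param spots A spot tibble.
#' @param layout An [array_layout()].
#' @return A tibble of issues with columns `issue` (`"under_replicated"`,
#'   `"over_replicated"`, `"unmapped_label"`, `"duplicate_position"`),
#'   `label`, `expected`, `observed`. Zero rows means fully conformant.
#' @export
validate_layout <- function(spots, layout) {
  stopifnot(inherits(layout, "array_layout"))
  expected <- layout_spots(layout) |>
    dplyr::count(.data$name, name = "expected")
  observed <- spots |> dplyr::count(.data$name, name = "observed")
  cmp <- dplyr::full_join(expected, observed, by = "name") |>
    dplyr::mutate(
      expected = tidyr::replace_na(.data$expected, 0L),
      observed = tidyr::replace_na(.data$observed, 0L)
    )
  issues <- dplyr::bind_rows(
    cmp |>
      dplyr::filter(.data$expected > 0, .data$observed < .data$expected,
                    .data$observed > 0 | .data$expected > 0) |>
      dplyr::filter(.data$observed < .data$expected) |>
      dplyr::mutate(issue = "under_replicated"),
    cmp |>
      dplyr::filter(.data$expected > 0, .data$observed > .data$expected) |>
      dplyr::mutate(issue = "over_replicated"),
    cmp |>
      dplyr::filter(.data$expected == 0) |>
      dplyr::mutate(issue = "unmapped_label")
  )
  dup <- spots |>
    dplyr::count(.data$block, .data$column, .data$row, name = "observed") |>
    dplyr::filter(.data$observed > 1)
  if (nrow(dup)) {
    issues <- dplyr::bind_rows(
      issues,
      tibble::tibble(
        name = sprintf("(%d,%d,%d)", dup$block, dup$column, dup$row),
        expected = 1L, observed = dup$observed, issue = "duplicate_position"
      )
    )
  }
  issues |>
    dplyr::transmute(issue = .data$issue, label = .data$name,
                     expected = .data$expected, observed = .data$observed)
}

#' Read a slide manifest
#'
#' A manifest maps per-array GPR files to their design metadata. CSV (columns
#' `file`, `slide_id`, `array_position`, `serum_id`, `day`, `dilution`;
#' `serum_id` empty or "MOCK" for mock arrays) and YAML (list of records with
#' the same fields) are accepted.
#'
#' @param path Manifest path (`.csv` or `.yaml`/`.yml`).
#' @return A tibble with one row per array file.
#' @export
read_manifest <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML manifests needs the 'yaml' package", call. = FALSE)
    }
    recs <- yaml::read_yaml(path)
    man <- purrr::map_dfr(recs, tibble::as_tibble)
  } else {
    man <- readr::read_csv(path, show_col_types = FALSE)
  }
  need <- c("file", "slide_id", "array_position")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"serum_id" %in% names(man)) man$serum_id <- NA_character_
  man |>
    dplyr::mutate(
      serum_id = dplyr::if_else(
        toupper(trimws(dplyr::coalesce(as.character(.data$serum_id), "MOCK"))) ==
          "MOCK",
        NA_character_, as.character(.data$serum_id)
      ),
      array_position = as.integer(.data$array_position)
    )
}
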