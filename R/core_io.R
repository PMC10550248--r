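SPECIMEN_COLUMNS <- c("specimen_id", "property", "sex", "molar_index",
                      "weight_kg", "pes_length_cm")
PROPERTY_LEVELS <- c("dingoes_common", "dingoes_rare")
SEX_LEVELS <- c("female", "male")
SITE_LEVELS <- c("north", "south")

#' Validate a specimen table and derive ages
#'
#' Checks the type invariants of a specimen table (known property/sex
#' levels, finite non-negative molar index, strictly positive weight and
#' pes length where present) and derives `age_days` / `age_years` from the
#' molar index. Rows failing an invariant are rejected with a located
#' diagnostic, never silently dropped.
#'
#' @param records Data frame with the specimen CSV columns.
#' @param age_scale Post-hoc multiplier passed to [age_from_molar_index()].
#' @return List with `records` (valid rows, ages attached) and `problems`
#'   (data frame of `row`, `column`, `message` for rejected rows).
#' @export
validate_specimens <- function(records, age_scale = 1) {
  missing_cols <- setdiff(SPECIMEN_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("specimen table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- list()
  note <- function(row, column, message) {
    problems[[length(problems) + 1L]] <<-
      data.frame(row = row, column = column, message = message,
                 stringsAsFactors = FALSE)
  }
  bad <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!r$property %in% PROPERTY_LEVELS) {
      note(i, "property", sprintf("unknown property '%s'", r$property)); bad[i] <- TRUE
    }
    if (!r$sex %in% SEX_LEVELS) {
      note(i, "sex", sprintf("unknown sex '%s'", r$sex)); bad[i] <- TRUE
    }
    if (!is.finite(r$molar_index) || r$molar_index < 0) {
      note(i, "molar_index", sprintf("molar index must be finite and >= 0, got %s",
                                     format(r$molar_index))); bad[i] <- TRUE
    }
    # NA means not measured (allowed); NaN flags an unparseable cell
    bad_weight <- is.nan(r$weight_kg) ||
      (!is.na(r$weight_kg) && (!is.finite(r$weight_kg) || r$weight_kg <= 0))
    if (bad_weight) {
      note(i, "weight_kg", sprintf("weight must be > 0, got %s",
                                   format(r$weight_kg))); bad[i] <- TRUE
    }
    bad_pes <- is.nan(r$pes_length_cm) ||
      (!is.na(r$pes_length_cm) &&
         (!is.finite(r$pes_length_cm) || r$pes_length_cm <= 0))
    if (bad_pes) {
      note(i, "pes_length_cm", sprintf("pes length must be > 0, got %s",
                                       format(r$pes_length_cm))); bad[i] <- TRUE
    }
  }
  ok <- records[!bad, , drop = FALSE]
  if (nrow(ok)) {
    ok$age_days <- age_from_molar_index(ok$molar_index, scale = age_scale)
    ok$age_years <- ok$age_days / 365.25
  } else {
    ok$age_days <- numeric(0)
    ok$age_years <- numeric(0)
  }
  rownames(ok) <- NULL
  list(
    records = ok,
    problems = if (length(problems)) do.call(rbind, problems) else
      data.frame(row = integer(0), column = character(0),
                 message = character(0), stringsAsFactors = FALSE)
  )
}

#' Read a specimen CSV
#'
#' Expects a delimited file with header columns `specimen_id, property,
#' sex, molar_index, weight_kg, pes_length_cm` (UTF-8, "." decimal,
#' configurable separator). Non-parseable numeric cells and invariant
#' violations are reported per row; offending rows are excluded from the
#' returned table.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @param age_scale See [validate_specimens()].
#' @param quiet Suppress the per-row diagnostics message.
#' @return Validated specimen data frame with derived `age_days`,
#'   `age_years`. The rejected-row report is attached as attribute
#'   `"problems"`.
#' @export
read_specimens <- function(path, sep = ",", age_scale = 1, quiet = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(SPECIMEN_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("specimen file ", path, " missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_problems <- list()
  parse_num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(x) & !(is.na(raw[[col]]) | raw[[col]] %in% c("", "NA"))
    for (i in which(bad)) {
      num_problems[[length(num_problems) + 1L]] <<- data.frame(
        row = i, column = col,
        message = sprintf("non-parseable numeric '%s'", raw[[col]][i]),
        stringsAsFactors = FALSE)
    }
    x[bad] <- NaN  # flagged so validate_specimens rejects the row too
    x
  }
  raw$molar_index <- parse_num("molar_index")
  raw$weight_kg <- parse_num("weight_kg")
  raw$pes_length_cm <- parse_num("pes_length_cm")
  v <- validate_specimens(raw, age_scale = age_scale)
  problems <- rbind(v$problems,
                    if (length(num_problems)) do.call(rbind, num_problems))
  if (nrow(problems) && !quiet) {
    message(sprintf("read_specimens: rejected %d row(s):", length(unique(problems$row))))
    for (i in seq_len(nrow(problems))) {
      message(sprintf("  row %d [%s]: %s", problems$row[i],
                      problems$column[i], problems$message[i]))
    }
  }
  attr(v$records, "problems") <- problems
  v$records
}

#' Write a specimen CSV
#'
#' Writes the canonical column set (derived age columns are not written;
#' they are recomputed on read).
#'
#' @param records Specimen data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_specimens <- function(records, path, sep = ",") {
  utils::write.table(records[, SPECIMEN_COLUMNS], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- landmark configurations -----------------------------------------------

#' Construct a landmark configuration
#'
#' @param specimen_id Specimen identifier.
#' @param coordinates k x 3 numeric matrix, no non-finite values, k >= 4.
#' @param labels Optional landmark labels (default `L1..Lk`).
#' @param pairing Optional pairing map from [make_pairing()].
#' @return Object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, coordinates, labels = NULL,
                            pairing = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be k x 3", call. = FALSE)
  if (nrow(coordinates) < 4L) stop("need at least 4 landmarks", call. = FALSE)
  if (any(!is.finite(coordinates))) {
    stop("coordinates contain non-finite values (specimen ", specimen_id, ")",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(coordinates)))
  stopifnot(length(labels) == nrow(coordinates))
  dimnames(coordinates) <- list(labels, c("x", "y", "z"))
  if (!is.null(pairing)) check_pairing(pairing, nrow(coordinates))
  structure(
    list(specimen_id = as.character(specimen_id), coordinates = coordinates,
         labels = labels, pairing = pairing),
    class = "landmark_config"
  )
}

#' Bilateral pairing map
#'
#' Describes the bilateral structure of a landmark scheme: index pairs
#' mirrored across the midsagittal plane plus unpaired midline indices.
#' Every landmark index must appear exactly once.
#'
#' @param pairs Two-column matrix of (left_index, right_index) pairs, or
#'   `NULL` if all landmarks are midline.
#' @param midline Integer vector of midline landmark indices.
#' @return Object of class `landmark_pairing`.
#' @export
make_pairing <- function(pairs, midline = integer(0)) {
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  midline <- as.integer(midline)
  structure(list(pairs = pairs, midline = midline), class = "landmark_pairing")
}

check_pairing <- function(pairing, k) {
  stopifnot(inherits(pairing, "landmark_pairing"))
  seen <- c(as.vector(pairing$pairs), pairing$midline)
  missing <- setdiff(seq_len(k), seen)
  if (length(missing)) {
    stop("pairing error: landmark index ", paste(missing, collapse = ", "),
         " present in neither pairs nor midline list", call. = FALSE)
  }
  if (anyDuplicated(seen)) {
    stop("pairing error: landmark index ",
         paste(unique(seen[duplicated(seen)]), collapse = ", "),
         " listed more than once", call. = FALSE)
  }
  if (any(seen < 1L | seen > k)) {
    stop("pairing error: index out of range 1..", k, call. = FALSE)
  }
  invisible(TRUE)
}

#' Read landmark configurations (TPS or long CSV)
#'
#' TPS records are `LM3=k` blocks of k lines of `x y z` followed by an
#' `ID=` line. The delimited alternative is a long CSV with columns
#' `specimen, landmark, x, y, z`. Landmark count must be consistent across
#' specimens. A pairing sidecar (see [read_pairing()]) can be attached.
#'
#' @param path Landmark file.
#' @param format `"tps"` or `"delimited"`.
#' @param pairing Optional `landmark_pairing` attached to every config.
#' @return List of `landmark_config`.
#' @export
read_landmarks <- function(path, format = c("tps", "delimited"),
                           pairing = NULL) {
  format <- match.arg(format)
  configs <- if (format == "tps") read_tps(path) else read_landmarks_long(path)
  ks <- vapply(configs, function(cf) nrow(cf$coordinates), integer(1))
  if (length(unique(ks)) > 1L) {
    stop("format error: inconsistent landmark count across specimens (",
         paste(unique(ks), collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(pairing)) {
    check_pairing(pairing, ks[1])
    configs <- lapply(configs, function(cf) { cf$pairing <- pairing; cf })
  }
  configs
}

read_tps <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    m <- regmatches(lines[i], regexec("^LM3=([0-9]+)$", lines[i]))[[1]]
    if (length(m) != 2L) stop("format error: expected LM3= record at line ",
                              i, " of ", path, call. = FALSE)
    k <- as.integer(m[2])
    if (i + k > length(lines)) stop("format error: truncated TPS record",
                                    call. = FALSE)
    coord_lines <- lines[(i + 1L):(i + k)]
    xyz <- do.call(rbind, lapply(strsplit(coord_lines, "[[:space:]]+"),
                                 as.numeric))
    if (ncol(xyz) != 3L || any(!is.finite(xyz))) {
      stop("format error: malformed coordinate block in ", path, call. = FALSE)
    }
    i <- i + k + 1L
    if (i > length(lines) || !startsWith(lines[i], "ID=")) {
      stop("format error: missing ID= line after coordinate block",
           call. = FALSE)
    }
    id <- sub("^ID=", "", lines[i])
    i <- i + 1L
    configs[[length(configs) + 1L]] <- landmark_config(id, xyz)
  }
  configs
}

read_landmarks_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "landmark", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("delimited landmark file needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, factor(df$specimen, levels = unique(df$specimen))),
         function(d) {
           d <- d[order(d$landmark), ]
           landmark_config(d$specimen[1], as.matrix(d[, c("x", "y", "z")]))
         })
}

#' Write landmark configurations as TPS
#'
#' @param configs List of `landmark_config`.
#' @param path Output path.
#' @param digits Coordinate print precision.
#' @export
write_tps <- function(configs, path, digits = 12) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    writeLines(sprintf("LM3=%d", nrow(cf$coordinates)), con)
    apply(cf$coordinates, 1, function(p) {
      writeLines(paste(formatC(p, digits = digits, format = "g"),
                       collapse = " "), con)
    })
    writeLines(paste0("ID=", cf$specimen_id), con)
  }
  invisible(path)
}

#' Read / write the pairing sidecar CSV
#'
#' Columns: `landmark_index, role, partner_index` with role in
#' `left,right,midline` (partner blank for midline).
#'
#' @param path Sidecar CSV path.
#' @return A `landmark_pairing`.
#' @export
read_pairing <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("landmark_index", "role", "partner_index")
  if (!all(need %in% names(df))) {
    stop("pairing sidecar needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lefts <- df[df$role == "left", ]
  make_pairing(cbind(lefts$landmark_index, lefts$partner_index),
               midline = df$landmark_index[df$role == "midline"])
}

#' @rdname read_pairing
#' @param pairing A `landmark_pairing` to serialize.
#' @export
write_pairing <- function(pairing, path) {
  rows <- rbind(
    if (nrow(pairing$pairs)) data.frame(landmark_index = pairing$pairs[, 1],
                                        role = "left",
                                        partner_index = pairing$pairs[, 2]),
    if (nrow(pairing$pairs)) data.frame(landmark_index = pairing$pairs[, 2],
                                        role = "right",
                                        partner_index = pairing$pairs[, 1]),
    if (length(pairing$midline)) data.frame(landmark_index = pairing$midline,
                                            role = "midline",
                                            partner_index = NA_integer_)
  )
  rows <- rows[order(rows$landmark_index), ]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---- vegetation-index observations -----------------------------------------

#' Read a long-format vegetation-index CSV
#'
#' Columns: `cell_id, lat, lon, date (ISO-8601), evi, site` with site in
#' `north,south`. Checks the 16-day (or stated) cadence per cell.
#'
#' @param path CSV path.
#' @param cadence_days Expected composite interval; `NA` skips the check.
#' @return Data frame of observations ordered by site, cell, date.
#' @export
read_evi <- function(path, cadence_days = 16) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "lat", "lon", "date", "evi", "site")
  if (!all(need %in% names(df))) {
    stop("EVI file needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$site %in% SITE_LEVELS)) {
    stop("site must be one of ", paste(SITE_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  df$date <- as.Date(df$date)
  if (any(is.na(df$date))) stop("non-parseable date in EVI file", call. = FALSE)
  df <- df[order(df$site, df$cell_id, df$date), ]
  if (!is.na(cadence_days)) {
    for (cid in unique(df$cell_id)) {
      d <- sort(unique(df$date[df$cell_id == cid]))
      if (length(d) > 1L && any(diff(as.integer(d)) != cadence_days)) {
        stop("cell ", cid, " violates the ", cadence_days, "-day cadence",
             call. = FALSE)
      }
    }
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_evi
#' @param observations EVI observation data frame to write.
#' @export
write_evi <- function(observations, path) {
  out <- observations[, c("cell_id", "lat", "lon", "date", "evi", "site")]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' Bundles the stage seeds, iteration counts and thresholds used by
#' [run_pipeline()]. All randomness in a run derives from `seed` via fixed
#' per-stage offsets, so a config + seed pair fully determines every
#' numeric output.
#'
#' @param seed Master integer seed.
#' @param n_perm_shape Permutations for the RRPP linear models.
#' @param n_iter_randomization Iterations for the vegetation randomization
#'   test.
#' @param window_length Moving-window length in composites (6 = 96 days).
#' @param alpha Significance threshold for interaction retention.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_perm_shape = 1000L,
                       n_iter_randomization = 10000L, window_length = 6L,
                       alpha = 0.05) {
  stopifnot(n_perm_shape >= 1L, n_iter_randomization >= 1L,
            window_length >= 1L, alpha > 0, alpha < 1)
  seed <- as.integer(seed)
  structure(
    list(
      seed = seed,
      seeds = list(specimens = seed + 101L, landmarks = seed + 202L,
                   evi = seed + 303L, perm = seed + 404L,
                   randomization = seed + 505L),
      n_perm_shape = as.integer(n_perm_shape),
      n_iter_randomization = as.integer(n_iter_randomization),
      window_length = as.integer(window_length),
      alpha = alpha
    ),
    class = "run_config"
  )
}
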