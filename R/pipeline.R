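#' Run configuration for batch trait analysis
#'
#' Inputs are validated on entry, mirroring interactive input checking:
#' invalid rows/cols/marker radius/k are rejected before any processing.
#'
#' @param rows,cols tray layout (pots per column/row).
#' @param marker_radius_mm physical radius of the red fiducial stickers
#'   (4 mm standard; 5 mm is the wheat preset).
#' @param species `"arabidopsis"` or `"wheat"`. Wheat series are analysed
#'   as single pots by convention and leaf-count fields are emitted empty
#'   (the counting heuristics do not transfer to wheat canopies).
#' @param k colour-group count 3--10, or `NULL`/`"auto"` to estimate it
#'   from the series midpoint image.
#' @param workers maximum number of series analysed concurrently.
#' @param seed RNG seed used for every stochastic step (clustering).
#' @param min_area_mm2 minimum object area kept in masks, mm^2.
#' @param save_debug_images write intermediate masks and the pot-grid
#'   overlay next to the CSV?
#' @param metadata_mode `"name"`, `"folder"` or `"none"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rows = 1L, cols = 1L, marker_radius_mm = NULL,
                            species = c("arabidopsis", "wheat"), k = NULL,
                            workers = 3L, seed = 42L, min_area_mm2 = 1,
                            save_debug_images = FALSE,
                            metadata_mode = c("name", "folder", "none")) {
  species <- match.arg(species)
  metadata_mode <- match.arg(metadata_mode)
  if (is.null(marker_radius_mm))
    marker_radius_mm <- if (species == "wheat") 5 else 4
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("'rows' and 'cols' must be integers >= 1")
  if (marker_radius_mm <= 0) stop("'marker_radius_mm' must be positive")
  if (identical(k, "auto")) k <- NULL
  if (!is.null(k)) {
    k <- as.integer(k)
    if (is.na(k) || k < 3L || k > 10L)
      stop("'k' must be in [3, 10] (or NULL/\"auto\")")
  }
  if (workers < 1L) stop("'workers' must be >= 1")
  structure(list(rows = rows, cols = cols,
                 marker_radius_mm = marker_radius_mm, species = species,
                 k = k, workers = as.integer(workers),
                 seed = as.integer(seed), min_area_mm2 = min_area_mm2,
                 save_debug_images = isTRUE(save_debug_images),
                 metadata_mode = metadata_mode),
            class = "pipeline_config")
}

# Filename convention: <ExpRef>_<TrayNo>_<YYYY-MM-DD[_HH-MM]>.<ext>
parse_image_name <- function(stem) {
  m <- regmatches(stem, regexec(
    "^(.+)_([A-Za-z0-9-]+)_(\\d{4}-\\d{2}-\\d{2})(?:_(\\d{2}-\\d{2}))?$",
    stem))[[1]]
  if (length(m) == 0L) return(NULL)
  tm <- if (m[5] != "") paste0(" ", sub("-", ":", m[5])) else " 12:00"
  list(exp_ref = m[2], tray_no = m[3],
       capture_time = as.POSIXct(paste0(m[4], tm), tz = "UTC"))
}

#' Discover image series and parse their metadata
#'
#' Groups the JPEG/PNG images of a directory into series. In `"name"` mode
#' the filename convention `<ExpRef>_<TrayNo>_<YYYY-MM-DD[_HH-MM]>.<ext>`
#' is parsed and images are grouped by (ExpRef, TrayNo); files that do not
#' match are routed to an `"unparsed"` series with a warning. In
#' `"folder"` mode each subdirectory is one series and the same convention
#' is applied to the directory name. In `"none"` mode all images form one
#' arbitrary series. Images are ordered by capture time when available,
#' else by name.
#'
#' @param input_dir directory containing the images (or series folders).
#' @param mode `"name"`, `"folder"` or `"none"`.
#' @return List of `series_job` objects: `metadata` (`exp_ref`, `tray_no`,
#'   `mode`), `images` (data.frame `path`, `capture_time`), `status`.
#' @export
parse_series_metadata <- function(input_dir,
                                  mode = c("name", "folder", "none")) {
  mode <- match.arg(mode)
  make_job <- function(exp_ref, tray_no, paths, times) {
    o <- if (!anyNA(times)) order(times, basename(paths)) else order(basename(paths))
    structure(list(
      metadata = list(exp_ref = exp_ref, tray_no = tray_no, mode = mode),
      images = data.frame(path = paths[o],
                          capture_time = times[o]),
      status = "not_processed"), class = "series_job")
  }
  if (mode == "folder") {
    subs <- list.dirs(input_dir, recursive = FALSE)
    subs <- subs[vapply(subs, function(d) length(list_image_files(d)) > 0,
                        logical(1))]
    if (length(subs) == 0L) subs <- input_dir
    jobs <- lapply(subs, function(d) {
      files <- list_image_files(d)
      meta <- parse_image_name(basename(d))
      pt <- lapply(basename(files), function(f)
        parse_image_name(tools::file_path_sans_ext(f)))
      times <- as.POSIXct(vapply(pt, function(p)
        if (is.null(p)) NA_real_ else as.numeric(p$capture_time),
        numeric(1)), origin = "1970-01-01", tz = "UTC")
      if (is.null(meta)) {
        warning("folder name not in convention: ", basename(d))
        meta <- list(exp_ref = "unparsed", tray_no = basename(d))
      }
      make_job(meta$exp_ref, meta$tray_no, files, times)
    })
    return(jobs)
  }
  files <- list_image_files(input_dir)
  if (length(files) == 0L) stop("no JPEG/PNG images found in ", input_dir)
  if (mode == "none") {
    return(list(make_job("series", "1", files,
                         as.POSIXct(rep(NA_real_, length(files)),
                                    origin = "1970-01-01", tz = "UTC"))))
  }
  parsed <- lapply(basename(files), function(f)
    parse_image_name(tools::file_path_sans_ext(f)))
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad))
    warning(sum(bad), " image name(s) not in convention; ",
            "routed to an 'unparsed' series")
  key <- vapply(seq_along(files), function(i)
    if (bad[i]) "unparsed\rNA" else
      paste(parsed[[i]]$exp_ref, parsed[[i]]$tray_no, sep = "\r"),
    character(1))
  jobs <- lapply(unique(key), function(kk) {
    sel <- key == kk
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    times <- as.POSIXct(vapply(which(sel), function(i)
      if (bad[i]) NA_real_ else as.numeric(parsed[[i]]$capture_time),
      numeric(1)), origin = "1970-01-01", tz = "UTC")
    make_job(parts[1], parts[2], files[sel], times)
  })
  jobs
}

#' Analyse one tray image
#'
#' Runs the full per-image chain: rescale to the 1024-px working height,
#' marker detection, scale, ROI extraction, denoising, global leaf
#' segmentation with the given `k`, pot split, per-pot refinement, traits
#' and leaf counts.
#'
#' @param img a [tray_image()] (or path to one).
#' @param cfg a [pipeline_config()].
#' @param k colour-group count for this series.
#' @return List with `rows` (one data.frame row per pot), `px_per_mm`, and
#'   (invisibly reusable) intermediates `roi`, `mask`, `regions`, `pots`.
#' @export
analyse_tray_image <- function(img, cfg, k) {
  if (is.character(img)) img <- read_plant_image(img)
  work <- rescale_to_height(img, 1024L)
  markers <- detect_reference_markers(work)
  scale <- compute_scale(markers, cfg$marker_radius_mm)
  roi <- denoise(extract_tray_roi(work, markers, scale))
  ccfg <- clustering_config(seed = cfg$seed)
  mask <- segment_leaves(roi, k, ccfg, cfg$min_area_mm2)
  regions <- build_pot_layout(dim(mask$mask), tray_layout(cfg$rows, cfg$cols))
  pots <- lapply(split_into_pots(mask, regions), refine_pot_mask,
                 img = roi, min_area_mm2 = cfg$min_area_mm2)
  wheat <- cfg$species == "wheat"
  rows <- lapply(pots, function(p) {
    tr <- measure_pot_traits(p, roi, scale)
    lcnt <- if (wheat) NULL else count_leaves(p, scale)
    data.frame(
      image_name = img$source_name,
      capture_time = if (is.null(img$capture_time)) as.POSIXct(NA) else
        img$capture_time,
      pot_id = p$region$index,
      px_per_mm = scale$px_per_mm,
      projected_leaf_area_mm2 = tr$area_mm2,
      leaf_perimeter_mm = tr$perimeter_mm,
      hull_area_mm2 = tr$hull_area_mm2,
      hull_length_mm = tr$hull_length_mm,
      hull_width_mm = tr$hull_width_mm,
      stockiness_pct = tr$stockiness_pct,
      compactness_pct = tr$compactness_pct,
      leaf_count = if (wheat) NA_integer_ else lcnt$combined,
      large_leaf_count = if (wheat) NA_integer_ else lcnt$large_leaves,
      greenness = tr$greenness
    )
  })
  list(rows = do.call(rbind, rows), px_per_mm = scale$px_per_mm,
       roi = roi, mask = mask, regions = regions, pots = pots)
}

#' Process one image series
#'
#' Estimates `k` from the series midpoint image (unless fixed in the
#' config), analyses every image, computes the per-pot daily relative
#' growth rate between consecutive successfully analysed images, and
#' returns the trait table. Images that fail any stage are logged and
#' skipped (the declined count is recorded); a series with no successful
#' image gets status `"failed"`.
#'
#' @param job a `series_job` from [parse_series_metadata()].
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory for debug images.
#' @return A `trait_table`: data.frame of per-(image, pot) records with
#'   attributes `status`, `log`, `declined`, `metadata`.
#' @export
process_series <- function(job, cfg, out_dir = NULL) {
  stopifnot(inherits(job, "series_job"), inherits(cfg, "pipeline_config"))
  logs <- character(0)
  note <- function(...) logs <<- c(logs, sprintf(...))
  paths <- job$images$path
  k <- cfg$k
  if (is.null(k)) {
    k <- tryCatch({
      sample_path <- select_sample_image(paths)
      simg <- rescale_to_height(read_plant_image(sample_path), 1024L)
      mk <- detect_reference_markers(simg)
      sroi <- extract_tray_roi(simg, mk, compute_scale(mk, cfg$marker_radius_mm))
      estimate_colour_groups(sroi, clustering_config(seed = cfg$seed))
    }, error = function(e) {
      note("k estimation failed (%s); using probe default 8",
           conditionMessage(e))
      8L
    })
    note("estimated k = %d from midpoint sample", k)
  }
  tables <- list()
  declined <- 0L
  for (i in seq_along(paths)) {
    res <- tryCatch({
      img <- read_plant_image(paths[i],
                              capture_time = job$images$capture_time[i])
      analyse_tray_image(img, cfg, k)
    }, error = function(e) {
      note("declined %s: %s", basename(paths[i]), conditionMessage(e))
      NULL
    })
    if (is.null(res)) { declined <- declined + 1L; next }
    tables[[length(tables) + 1L]] <- res$rows
    if (cfg$save_debug_images && !is.null(out_dir))
      save_debug_images(res, basename(paths[i]), out_dir)
  }
  note("processed %d image(s), declined %d", length(tables), declined)
  if (length(tables) == 0L) {
    tab <- empty_trait_table()
    attr(tab, "status") <- "failed"
  } else {
    tab <- do.call(rbind, tables)
    tab <- cbind(
      image_name = tab$image_name, capture_time = tab$capture_time,
      exp_ref = job$metadata$exp_ref, tray_no = job$metadata$tray_no,
      tab[, !(names(tab) %in% c("image_name", "capture_time"))])
    tab$daily_rgr <- series_rgr(tab)
    attr(tab, "status") <- "done"
  }
  attr(tab, "log") <- logs
  attr(tab, "declined") <- declined
  attr(tab, "metadata") <- job$metadata
  class(tab) <- c("trait_table", "data.frame")
  tab
}

empty_trait_table <- function() {
  data.frame(image_name = character(), capture_time = as.POSIXct(character()),
             exp_ref = character(), tray_no = character(),
             pot_id = integer(), px_per_mm = numeric(),
             projected_leaf_area_mm2 = numeric(), leaf_perimeter_mm = numeric(),
             hull_area_mm2 = numeric(), hull_length_mm = numeric(),
             hull_width_mm = numeric(), stockiness_pct = numeric(),
             compactness_pct = numeric(), leaf_count = integer(),
             large_leaf_count = integer(), greenness = numeric(),
             daily_rgr = numeric())
}

# Daily RGR per pot between consecutive images, in table order. Capture
# times give dt in days; without timestamps consecutive images are one day
# apart. Undefined cases (first image, empty pots, 1 mm^2 singularity)
# are NA.
series_rgr <- function(tab) {
  rgr <- rep(NA_real_, nrow(tab))
  imgs <- unique(tab$image_name)
  for (pot in unique(tab$pot_id)) {
    sel <- which(tab$pot_id == pot)
    sel <- sel[order(match(tab$image_name[sel], imgs))]
    for (j in seq_along(sel)[-1]) {
      a1 <- tab$projected_leaf_area_mm2[sel[j - 1]]
      a2 <- tab$projected_leaf_area_mm2[sel[j]]
      t1 <- tab$capture_time[sel[j - 1]]
      t2 <- tab$capture_time[sel[j]]
      dt <- if (!is.na(t1) && !is.na(t2))
        as.numeric(difftime(t2, t1, units = "days")) else j - (j - 1)
      if (dt <= 0) dt <- 1
      if (a1 > 0 && a2 > 0)
        rgr[sel[j]] <- daily_rgr(a1, a2, dt)
    }
  }
  rgr
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("<trait_table> %s / tray %s: %d rows (%s), %d declined\n",
              attr(x, "metadata")$exp_ref, attr(x, "metadata")$tray_no,
              nrow(x), attr(x, "status"), attr(x, "declined")))
  invisible(x)
}

#' Process several series with bounded concurrency
#'
#' At most `workers` series (default 3) run concurrently as forked
#' processes; results are collected in job order and are independent of the
#' worker count and scheduling, because every stochastic step uses the
#' fixed configuration seed. The observed peak concurrency is recorded in
#' the `"peak_concurrency"` attribute of the result.
#'
#' @param jobs list of `series_job` objects.
#' @param cfg a [pipeline_config()].
#' @param out_dir optional output directory passed to [process_series()].
#' @param workers overrides `cfg$workers` when given.
#' @return List of `trait_table`s, attribute `peak_concurrency`.
#' @export
run_batch <- function(jobs, cfg, out_dir = NULL, workers = NULL) {
  if (is.null(workers)) workers <- cfg$workers
  n <- length(jobs)
  results <- vector("list", n)
  if (workers <= 1L || n <= 1L ||
      .Platform$OS.type != "unix") {
    for (i in seq_len(n))
      results[[i]] <- process_series(jobs[[i]], cfg, out_dir)
    attr(results, "peak_concurrency") <- min(1L, n)
    return(results)
  }
  active <- list()   # name -> job index
  nxt <- 1L
  peak <- 0L
  while (nxt <= n || length(active) > 0L) {
    while (nxt <= n && length(active) < workers) {
      ph <- parallel::mcparallel(process_series(jobs[[nxt]], cfg, out_dir))
      active[[as.character(ph$pid)]] <- list(handle = ph, idx = nxt)
      nxt <- nxt + 1L
    }
    peak <- max(peak, length(active))
    got <- parallel::mccollect(lapply(active, `[[`, "handle"),
                               wait = FALSE, timeout = 0.2)
    if (!is.null(got)) {
      for (pid in names(got)) {
        if (is.null(got[[pid]])) next
        slot <- active[[pid]]
        if (is.null(slot)) next
        results[[slot$idx]] <- got[[pid]]
        active[[pid]] <- NULL
      }
    }
  }
  attr(results, "peak_concurrency") <- peak
  results
}

#' Write a trait table as CSV
#'
#' One CSV per series, with the fixed header
#' `image_name,capture_time,exp_ref,tray_no,pot_id,px_per_mm,projected_leaf_area_mm2,leaf_perimeter_mm,hull_area_mm2,hull_length_mm,hull_width_mm,stockiness_pct,compactness_pct,leaf_count,large_leaf_count,greenness,daily_rgr`.
#' Floating values carry 3 decimals; undefined values (absent RGR, wheat
#' leaf counts) are empty fields.
#'
#' @param table a `trait_table`.
#' @param out_dir output directory (created if needed).
#' @return The CSV path, invisibly.
#' @export
write_trait_csv <- function(table, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  md <- attr(table, "metadata")
  fname <- sprintf("%s_%s_traits.csv",
                   gsub("[^A-Za-z0-9._-]", "-", md$exp_ref),
                   gsub("[^A-Za-z0-9._-]", "-", md$tray_no))
  path <- file.path(out_dir, fname)
  num3 <- function(v) ifelse(is.na(v), "", formatC(v, format = "f",
                                                   digits = 3))
  int0 <- function(v) ifelse(is.na(v), "", as.character(v))
  lines <- c(paste(trait_csv_columns(), collapse = ","))
  if (nrow(table) > 0) {
    body <- paste(
      table$image_name,
      ifelse(is.na(table$capture_time), "",
             format(table$capture_time, "%Y-%m-%d %H:%M", tz = "UTC")),
      table$exp_ref, table$tray_no, table$pot_id,
      num3(table$px_per_mm), num3(table$projected_leaf_area_mm2),
      num3(table$leaf_perimeter_mm), num3(table$hull_area_mm2),
      num3(table$hull_length_mm), num3(table$hull_width_mm),
      num3(table$stockiness_pct), num3(table$compactness_pct),
      int0(table$leaf_count), int0(table$large_leaf_count),
      num3(table$greenness), num3(table$daily_rgr), sep = ",")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

trait_csv_columns <- function() {
  c("image_name", "capture_time", "exp_ref", "tray_no", "pot_id",
    "px_per_mm", "projected_leaf_area_mm2", "leaf_perimeter_mm",
    "hull_area_mm2", "hull_length_mm", "hull_width_mm", "stockiness_pct",
    "compactness_pct", "leaf_count", "large_leaf_count", "greenness",
    "daily_rgr")
}

# Debug dumps: global mask and a grid overlay with pot indices.
save_debug_images <- function(res, stem, out_dir) {
  dbg <- file.path(out_dir, "debug")
  dir.create(dbg, recursive = TRUE, showWarnings = FALSE)
  stem <- tools::file_path_sans_ext(stem)
  write_plant_image(res$mask$mask * 255,
                    file.path(dbg, paste0(stem, "_mask.png")))
  ov <- res$roi$pixels
  for (rg in res$regions) {
    bb <- rg$bbox
    ov[bb[1], bb[2]:bb[4], ] <- 255
    ov[bb[1]:bb[3], bb[2], ] <- 255
    ov <- draw_number(ov, rg$index, bb[1] + 4, bb[2] + 4)
  }
  write_plant_image(ov, file.path(dbg, paste0(stem, "_grid.png")))
  invisible(NULL)
}

# 3x5 bitmap digits for the grid overlay.
digit_glyphs <- function() {
  g <- list(
    "0" = c("111","101","101","101","111"), "1" = c("010","110","010","010","111"),
    "2" = c("111","001","111","100","111"), "3" = c("111","001","111","001","111"),
    "4" = c("101","101","111","001","001"), "5" = c("111","100","111","001","111"),
    "6" = c("111","100","111","101","111"), "7" = c("111","001","010","010","010"),
    "8" = c("111","101","111","101","111"), "9" = c("111","101","111","001","111"))
  g
}

draw_number <- function(px, num, y, x) {
  glyphs <- digit_glyphs()
  for (d in strsplit(as.character(num), "")[[1]]) {
    gl <- glyphs[[d]]
    for (r in 1:5) for (c in 1:3) {
      if (substr(gl[r], c, c) == "1" &&
          y + r <= dim(px)[1] && x + c <= dim(px)[2]) {
        px[y + r, x + c, 1] <- 255
        px[y + r, x + c, 2] <- 255
        px[y + r, x + c, 3] <- 0
      }
    }
    x <- x + 4
  }
  px
}
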