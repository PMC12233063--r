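#' Write a grid table to CSV
#'
#' Serializes a `hexgrid` as the per-ommatidium table: `ommatidium_id`,
#' `x_hex`, `y_hex`, `x_px`, `y_px`, `z_um`, `column_index`, `origin`.
#' Floats are written with 17 significant digits so that
#' `read_grid(write_grid(g))` round-trips bit-exactly.
#'
#' @param grid A `hexgrid` (or a data frame in the table schema).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_grid <- function(grid, path) {
  tab <- if (inherits(grid, "hexgrid")) {
    data.frame(ommatidium_id = seq_len(nrow(grid$omm)),
               x_hex = grid$omm$x_hex, y_hex = grid$omm$y_hex,
               x_px = grid$omm$x, y_px = grid$omm$y,
               z_um = grid$omm$z,
               column_index = grid$omm$x_hex + grid$omm$y_hex,
               origin = grid$omm$origin)
  } else grid
  num <- function(v) ifelse(is.na(v), "", formatC(v, digits = 17,
                                                  format = "g"))
  lines <- c(paste(names(tab), collapse = ","),
             paste(tab$ommatidium_id, tab$x_hex, tab$y_hex,
                   num(tab$x_px), num(tab$y_px), num(tab$z_um),
                   tab$column_index, tab$origin, sep = ","))
  if (nrow(tab) == 0) lines <- lines[1]
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a grid table from CSV
#'
#' @param path CSV written by [write_grid].
#' @return A `hexgrid`. Duplicate hexagonal coordinates are an error naming
#'   the offending rows.
#' @export
read_grid <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(ommatidium_id = "integer",
                                 x_hex = "integer", y_hex = "integer",
                                 x_px = "numeric", y_px = "numeric",
                                 z_um = "numeric",
                                 column_index = "integer",
                                 origin = "character"))
  keys <- hex_key(tab$x_hex, tab$y_hex)
  dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  if (any(dup))
    stop("duplicate (x_hex, y_hex) in ", path, " at rows: ",
         paste(which(dup), collapse = ", "))
  new_hexgrid(data.frame(
    id = tab$ommatidium_id, x_hex = tab$x_hex, y_hex = tab$y_hex,
    x = tab$x_px, y = tab$y_px, z = tab$z_um,
    slant = rep(NA_real_, nrow(tab)),
    origin = tab$origin, stringsAsFactors = FALSE))
}

#' Label image of a segmented grid
#'
#' Assigns every eye-mask pixel the id of the nearest ommatidium center and
#' zeroes a 1-px boundary between adjacent labels, producing the facet /
#' boundary label image (0 = background or boundary, k = ommatidium k).
#'
#' @param grid A non-empty `hexgrid`.
#' @param eye_mask Logical matrix.
#' @return Integer matrix of labels.
#' @export
write_labels <- function(grid, eye_mask) {
  stopifnot(inherits(grid, "hexgrid"), nrow(grid$omm) >= 1,
            is.matrix(eye_mask))
  H <- nrow(eye_mask); W <- ncol(eye_mask)
  nn <- cpp_nearest2(grid$omm$x, grid$omm$y, W, H)
  lab <- nn$label
  lab[!eye_mask] <- 0L
  # 1-px boundary between adjacent distinct labels
  bnd <- matrix(FALSE, H, W)
  a <- lab[-H, ]; b <- lab[-1, ]
  sel <- a != b & a > 0 & b > 0
  bnd[-H, ][sel] <- TRUE
  a <- lab[, -W]; b <- lab[, -1]
  sel <- a != b & a > 0 & b > 0
  bnd[, -W][sel] <- TRUE
  lab[bnd] <- 0L
  lab
}

#' Write / read a 16-bit label TIFF
#'
#' @param labels Integer matrix (< 65536 labels).
#' @param path Output path.
#' @return Invisibly `path` / the integer label matrix.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) < 65536)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' Run the full segmentation pipeline
#'
#' Chains focus stacking, classification (or ideal maps), hexagonal grid
#' expansion and morphometric analysis, persisting intermediate artifacts and
#' a machine-readable run report. Any stage failure aborts with the stage
#' name.
#'
#' @param config A list:
#'   \describe{
#'     \item{image / stack}{a grayscale matrix, an `image_stack`, or a file
#'       path loadable by [load_stack]}
#'     \item{maps}{precomputed [probability_maps] (skips classification)}
#'     \item{models}{list with `eye` and `facet` `pixel_model`s}
#'     \item{seeds}{3 x 2 matrix of seed positions, or `"auto"`}
#'     \item{px_size}{um/px (required for micrometer outputs)}
#'     \item{anterior}{anterior direction (default `"right"`)}
#'     \item{z_step}{focal step, um (default 8)}
#'     \item{window}{focus window (default 9)}
#'     \item{fit}{a [fit_config]}
#'     \item{out_dir}{output directory (optional; no files written if `NULL`)}
#'   }
#' @return List with `grid` (reindexed `hexgrid`), `maps`, `labels`,
#'   `profile`, `spacing`, `report` (list of counts and expansion
#'   statistics).
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  altitude <- NULL
  img <- NULL
  if (!is.null(config$image) || !is.null(config$stack)) {
    src <- config$image %||% config$stack
    stk <- stage("focus", {
      if (is.character(src)) src <- load_stack(src, config$z_step %||% 8)
      if (is.matrix(src)) src <- new_image_stack(list(src),
                                                 config$z_step %||% 8)
      src
    })
    foc <- stage("focus", focus_stack(stk, config$window %||% 9))
    img <- foc$image
    altitude <- altitude_map(foc, stk$z_step)
    say("focus: %d plane(s) -> %d x %d focused image",
        length(stk$planes), ncol(img), nrow(img))
  }
  maps <- if (!is.null(config$maps)) config$maps else stage("classify", {
    if (is.null(config$models)) stop("missing model (no maps supplied)")
    predict_maps(img, config$models$eye, config$models$facet)
  })
  say("classify: eye mask %d px", sum(maps$eye_mask))
  grid0 <- stage("segment", {
    if (identical(config$seeds, "auto") || is.null(config$seeds))
      auto_seed(maps)
    else seed_grid(config$seeds[1, ], config$seeds[2, ], config$seeds[3, ])
  })
  grid <- stage("segment", expand_grid(grid0, maps,
                                       config$fit %||% fit_config()))
  stats <- attr(grid, "stats")
  say("segment: %d ommatidia (%d added, %d proposals rejected), L_grid %.2f",
      nrow(grid$omm), stats$n_added, stats$n_rejected, stats$L_grid)
  grid <- stage("analyze", {
    if (!is.null(altitude))
      grid <- assign_altitude(grid, altitude, config$px_size %||% 1)
    recenter_and_orient(grid, config$anterior %||% "right")
  })
  profile <- column_profile(grid)
  spacing <- spacing_per_ommatidium(grid, px_size = config$px_size %||% 1)
  labels <- write_labels(grid, maps$eye_mask)
  cnt <- count_ommatidia(grid)
  report <- list(count = unname(cnt["n"]), columns = unname(cnt["columns"]),
                 L_grid = stats$L_grid, n_added = stats$n_added,
                 n_rejected = stats$n_rejected, n_fits = stats$n_fits,
                 mean_spacing = mean(spacing$spacing, na.rm = TRUE))
  say("analyze: %d columns, mean spacing %.2f", report$columns,
      report$mean_spacing)
  if (!is.null(out_dir)) {
    write_grid(grid, file.path(out_dir, "grid.csv"))
    write_label_tiff(labels, file.path(out_dir, "labels.tif"))
    png::writePNG(maps$eye_mask * 1, file.path(out_dir, "eye_mask.png"))
    tiff::writeTIFF(maps$eye_prob, file.path(out_dir, "eye_prob.tif"),
                    bits.per.sample = 16L, compression = "none")
    tiff::writeTIFF(maps$facet_prob, file.path(out_dir, "facet_prob.tif"),
                    bits.per.sample = 16L, compression = "none")
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    resolved <- config[!vapply(config, function(x)
      is.matrix(x) || is.list(x) && !inherits(x, "fit_config"), logical(1))]
    jsonlite::write_json(resolved, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  list(grid = grid, maps = maps, labels = labels, profile = profile,
       spacing = spacing, report = report)
}

#' Scripted correction of a segmented grid against a reference table
#'
#' Batch (non-interactive) equivalent of manual correction: registrations
#' with no reference center within `tol` are removed; reference centers with
#' no registration within `tol` are added via [add_manual] (each receives an
#' automatically inferred hex coordinate).
#'
#' @param grid A `hexgrid`.
#' @param ref_centers n x 2 matrix of reference positions (px).
#' @param tol Matching radius in px (default half the grid edge length).
#' @return The corrected `hexgrid`, with attribute `correction` (counts of
#'   removed/added).
#' @export
correct_grid <- function(grid, ref_centers, tol = NULL) {
  stopifnot(inherits(grid, "hexgrid"))
  ref_centers <- as.matrix(ref_centers)
  L <- grid_edge_length(grid)
  tol <- tol %||% (L / 2)
  # greedy one-to-one matching, closest pairs first
  omm <- grid$omm
  dmat <- outer(omm$x, ref_centers[, 1], "-")^2 +
    outer(omm$y, ref_centers[, 2], "-")^2
  matched_g <- logical(nrow(omm)); matched_r <- logical(nrow(ref_centers))
  ord <- order(dmat)
  for (k in ord) {
    if (dmat[k] > tol^2) break
    i <- (k - 1) %% nrow(omm) + 1
    j <- (k - 1) %/% nrow(omm) + 1
    if (matched_g[i] || matched_r[j]) next
    matched_g[i] <- TRUE; matched_r[j] <- TRUE
  }
  n_rm <- sum(!matched_g)
  for (i in which(!matched_g))
    grid <- remove_ommatidium(grid, c(omm$x_hex[i], omm$y_hex[i]))
  n_add <- sum(!matched_r)
  for (j in which(!matched_r))
    grid <- add_manual(grid, ref_centers[j, ])
  attr(grid, "correction") <- list(removed = n_rm, added = n_add)
  grid
}
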