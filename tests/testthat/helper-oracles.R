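# Independent oracles and fixture builders used across the suite.

# Brute-force Kendall tau by explicit pair enumeration; NA entries dropped
# with original order retained. Deliberately naive and separate from the
# package's compiled implementation.
tau_oracle <- function(x, convention = "b") {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(NA_real_)
  conc <- disc <- tied <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] > x[i]) conc <- conc + 1
      else if (x[j] < x[i]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  n0 <- n * (n - 1) / 2
  denom <- if (convention == "b") sqrt((n0 - tied) * n0) else n0
  if (denom == 0) return(0)
  (conc - disc) / denom
}

# Textbook Welch t statistic and two-sided p.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

# Brute-force ring assignment: exact distance from every cell centroid to
# the union of grove-pixel square footprints, minimised over grove pixels
# directly (no window shortcuts).
ring_oracle <- function(grove_set, grid, K, ring_width = 30) {
  nc <- grid$n_rows * grid$n_cols
  ctr <- cell_centroids(grid)
  g <- which(grove_set)
  h <- grid$pixel_size / 2
  d <- rep(Inf, nc)
  for (gi in g) {
    gc <- cell_centroids(grid, gi)
    dx <- pmax(0, abs(ctr[, 1] - gc[1]) - h)
    dy <- pmax(0, abs(ctr[, 2] - gc[2]) - h)
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  ring <- rep(NA_integer_, nc)
  fin <- is.finite(d) & d <= K * ring_width
  ring[fin] <- as.integer(ceiling(d[fin] / ring_width - 1e-9))
  ring[grove_set] <- 0L
  ring
}

# GeoJSON text for a FeatureCollection of polygon rings (list of n x 2
# matrices, one shell per feature).
write_geojson_rects <- function(rings, path, ids = NULL,
                                crs = "EPSG:32637") {
  feats <- lapply(seq_along(rings), function(k) {
    r <- rings[[k]]
    r <- rbind(r, r[1, , drop = FALSE])
    coords <- paste(sprintf("[%s,%s]", r[, 1], r[, 2]), collapse = ",")
    id <- if (is.null(ids)) as.character(k) else ids[[k]]
    sprintf('{"type":"Feature","id":"%s","properties":{},"geometry":{"type":"Polygon","coordinates":[[%s]]}}',
            id, coords)
  })
  txt <- sprintf('{"type":"FeatureCollection","crs":{"type":"name","properties":{"name":"%s"}},"features":[%s]}',
                 crs, paste(feats, collapse = ","))
  writeLines(txt, path)
  path
}

rect_ring <- function(x0, y0, w, h) {
  rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
}

# small monthly series with a hand-built value matrix
make_monthly <- function(values, n_rows = NULL, start = c(2000, 1)) {
  values <- as.matrix(values)
  if (is.null(n_rows)) n_rows <- nrow(values)
  grid <- grid_spec(n_rows, nrow(values) / n_rows)
  nm <- ncol(values)
  ym <- (start[1] * 12L + start[2] - 1L) + seq_len(nm) - 1L
  monthly_series(grid, ym %/% 12L, ym %% 12L + 1L, values)
}

# builds a trend_map + pixel_classes pair directly from a tau vector and
# ring labels, bypassing the raster pipeline (the inference layer only
# sees taus and labels)
fake_scene <- function(taus_by_class, K = max(as.integer(sub("ring_", "",
                         grep("^ring_", names(taus_by_class), value = TRUE))))) {
  n <- sum(lengths(taus_by_class))
  nr <- ceiling(sqrt(n))
  grid <- grid_spec(nr, ceiling(n / nr))
  ncell <- nr * ceiling(n / nr)
  label <- integer(ncell)
  tau <- rep(NA_real_, ncell)
  i <- 1L
  for (nm in names(taus_by_class)) {
    code <- switch(sub("_[0-9]+$", "", nm),
                   grove = 1L,
                   ring = 1L + as.integer(sub("ring_", "", nm)),
                   other_agri = 255L,
                   excluded = 0L)
    v <- taus_by_class[[nm]]
    if (length(v) == 0) next
    label[i:(i + length(v) - 1L)] <- code
    tau[i:(i + length(v) - 1L)] <- v
    i <- i + length(v)
  }
  code_table <- data.frame(
    code = c(0L, 1L, 1L + seq_len(K), 255L),
    label = c("excluded", "grove", paste0("ring_", seq_len(K)), "other_agri"),
    stringsAsFactors = FALSE)
  pc <- structure(list(grid = grid, label = label, K = as.integer(K),
                       ring_width = 30, code_table = code_table),
                  class = "pixel_classes")
  tm <- structure(list(grid = grid, tau = tau,
                       n_valid = ifelse(is.na(tau), 0L, 229L),
                       class_label = classify_trend(tau),
                       min_points = 24L, convention = "b"),
                  class = "trend_map")
  list(trend = tm, classes = pc)
}

# desk-scale scenario used by simulation-heavy tests: the default study
# conditions at monthly-equivalent cadence
desk_scenario <- function(seed, ...) {
  scenario(cadence = "monthly", seed = seed, ...)
}

quiet_scene <- function(sc) suppressWarnings(simulate_scene(sc))

# the standard staged run shared by simulation tests
run_scene_fit <- function(sc, min_valid_in_window = 10) {
  scene <- quiet_scene(sc)
  sm <- preprocess_stack(scene$stack, min_valid_in_window = min_valid_in_window)
  gpx <- grove_pixels(scene$groves, scene$grid)
  pc <- classify_pixels(gpx, distance_rings(gpx, scene$grid), scene$mask)
  tr <- trend_map(sm, cells = which(pc$label >= 1L))
  suppressWarnings(spillover_fit(tr, pc))
}
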