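test_that("grove pixel rule: centroid within 15 m of the polygon", {
  g <- grid_spec(5, 5)
  # polygon covering cell (3,3): x,y in [60, 90]; neighbour centroids are
  # 15 m from its edge, next-over centroids 45 m
  gs <- grove_set(list(list(rect_ring(60, 60, 30, 30))), "g")
  hit <- which(grove_pixels(gs, g))
  # orthogonal neighbour centroids are exactly 15 m from the edge (in);
  # diagonal centroids are 21.2 m from the corner (out)
  expect_setequal(hit, c(cell_index(g, 3L, 3L),
                         cell_index(g, c(2L, 4L), 3L),
                         cell_index(g, 3L, c(2L, 4L))))

  # 20 m outside the edge -> not grove
  gs2 <- grove_set(list(list(rect_ring(65, 60, 20, 30))), "g")  # edges at x=65,85
  hit2 <- grove_pixels(gs2, g)
  expect_true(hit2[cell_index(g, 3L, 3L)])    # centroid (75,75) inside
  expect_false(hit2[cell_index(g, 3L, 2L)])   # centroid (45,75): 20 m out
})

test_that("grove buffer distances are exact at 10 m and 20 m", {
  g <- grid_spec(3, 3)
  # rectangle x in [55, 80], all rows: centroid col1 (15,.) is 40 m out;
  # col2 centroid (45,.) is 10 m out; col3 centroid (75,.) inside
  gs <- grove_set(list(list(rect_ring(55, 0, 25, 90))), "g")
  hit <- grove_pixels(gs, g)
  expect_true(all(hit[cell_index(g, 1:3, 3L)]))   # inside
  expect_true(all(hit[cell_index(g, 1:3, 2L)]))   # 10 m outside edge
  expect_false(any(hit[cell_index(g, 1:3, 1L)]))  # 40 m outside
  gs2 <- grove_set(list(list(rect_ring(65, 0, 15, 90))), "g")  # edge at x=65
  expect_false(any(grove_pixels(gs2, g)[cell_index(g, 1:3, 1L)]))  # 50 m
  gs3 <- grove_set(list(list(rect_ring(25, 0, 10, 90))), "g")  # edge at 35
  expect_true(all(grove_pixels(gs3, g)[cell_index(g, 1:3, 1L)]))  # 20 m? no:
  # centroid x = 15, edge at 25 -> 10 m -> grove. And col2 centroid 45 is
  # 10 m from edge 35 -> also grove.
  expect_true(all(grove_pixels(gs3, g)[cell_index(g, 1:3, 2L)]))
})

test_that("ring 1 of an isolated grove pixel is exactly its 8 neighbours", {
  g <- grid_spec(7, 7)
  grove <- logical(49); grove[cell_index(g, 4L, 4L)] <- TRUE
  rings <- distance_rings(grove, g, K = 2)
  r1 <- which(rings == 1L)
  expect_setequal(r1, setdiff(as.vector(outer(3:5, (3:5 - 1L) * 7L, `+`)),
                              cell_index(g, 4L, 4L)))
  # footprint distances: orthogonal 15 m, diagonal ~21.2 m, next-over 45 m
  expect_equal(sum(rings == 1L, na.rm = TRUE), 8)
  # ring1 + ring2 = all centroids within 60 m of the footprint
  r12 <- which(rings %in% c(1L, 2L))
  d <- greenspill:::grove_distance(grove, g, max_dist = 60)
  expect_setequal(r12, setdiff(which(d <= 60), which(grove)))
})

test_that("rings are exclusive, exhaustive over the buffer, and translation invariant", {
  set.seed(201)
  g <- grid_spec(40, 40)
  grove <- logical(1600)
  grove[sample(1600, 12)] <- TRUE
  K <- 5
  rings <- distance_rings(grove, g, K = K)
  oracle <- ring_oracle(grove, g, K)
  expect_identical(rings, oracle)
  # no pixel in two rings by construction; grove never ringed
  expect_true(all(rings[grove] == 0L))

  # translation by whole pixels only relabels cells
  shift <- 3L
  grove2 <- logical(1600)
  idx <- which(grove)
  r <- (idx - 1L) %% 40L + 1L; cc <- (idx - 1L) %/% 40L + 1L
  keep <- r + shift <= 40L & cc + shift <= 40L
  grove2[cell_index(g, r[keep] + shift, cc[keep] + shift)] <- TRUE
  rings2 <- distance_rings(grove2, g, K = K)
  inner <- which(r > shift & cc > shift & r <= 40L - shift & cc <= 40L - shift)
  for (i in inner[1:min(50, length(inner))]) {
    expect_identical(rings2[cell_index(g, r[i] + shift, cc[i] + shift)],
                     rings[idx[i]])
  }
})

test_that("minimum centroid-to-grove distance in ring k lies in ((k-1)w, kw]", {
  set.seed(202)
  g <- grid_spec(60, 60)
  grove <- logical(3600); grove[sample(3600, 20)] <- TRUE
  K <- 6
  rings <- distance_rings(grove, g, K = K)
  d <- greenspill:::grove_distance(grove, g, max_dist = K * 30)
  for (k in seq_len(K)) {
    dk <- d[which(rings == k)]
    expect_true(all(dk > (k - 1) * 30 & dk <= k * 30 + 1e-9))
  }
})

test_that("classification precedence and area accounting are correct", {
  g <- grid_spec(30, 30, crs_id = "EPSG:32637")
  grove <- logical(900); grove[cell_index(g, 15L, 15L)] <- TRUE
  # non-agricultural block (a national park) overlapping ring 3
  agri <- rep(TRUE, 900)
  agri[cell_index(g, 15L, 18L)] <- FALSE   # 90 m away: in ring 3
  agri[cell_index(g, 1L, 1L)] <- FALSE     # far corner: excluded
  mask <- study_mask(g, agri, rep(TRUE, 900))
  pc <- classify_pixels(grove, NULL, mask, K = 3)
  lab <- pc$label
  expect_equal(lab[cell_index(g, 15L, 15L)], 1L)          # grove
  expect_equal(lab[cell_index(g, 15L, 16L)], 2L)          # ring 1
  expect_equal(lab[cell_index(g, 15L, 18L)], 4L)          # park pixel ringed
  expect_equal(lab[cell_index(g, 1L, 1L)], 0L)            # excluded
  expect_equal(lab[cell_index(g, 15L, 25L)], 255L)        # beyond K rings
  # exactly one label per study-area pixel (codes partition the scene)
  expect_true(all(lab %in% c(0L, 1L, 2L, 3L, 4L, 255L)))

  expect_equal(area_ha(pc, "grove"), 0.09)
  expect_equal(area_ha(pc, "ring_1"), 8 * 0.09)
  # 100 pixels at 30 m are 9 ha
  expect_equal(100 * g$pixel_size^2 / 1e4, 9)
  expect_error(area_ha(pc, "ring_99"), "unknown class label")
})

test_that("centroid-buffer variant drops the diagonal neighbours", {
  g <- grid_spec(7, 7)
  grove <- logical(49); grove[cell_index(g, 4L, 4L)] <- TRUE
  rings <- distance_rings(grove, g, K = 1, buffer_of = "centroid")
  expect_equal(sum(rings == 1L, na.rm = TRUE), 4)  # orthogonal only at 30 m
})
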