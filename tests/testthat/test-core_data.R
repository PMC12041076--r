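test_that("read_spots keeps panel genes, drops off-panel rows, round-trips", {
  panel <- gene_panel()
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(gene = c("Mbp", "Plp1", "NotAGene", "App"),
                   x = 1:4, y = 5:8, cell_id = c(1, 1, 2, 2))
  write.csv(df, f, row.names = FALSE)
  expect_message(sp <- read_spots(f, panel, sample_id = "s1"), "1 spot")
  expect_equal(nrow(sp), 3)
  expect_equal(attr(sp, "dropped_off_panel"), 1)
  expect_setequal(sp$gene, c("Mbp", "Plp1", "App"))

  # all-panel file passes through unchanged
  write.csv(df[df$gene != "NotAGene", ], f, row.names = FALSE)
  sp2 <- read_spots(f, panel, sample_id = "s1")
  expect_equal(nrow(sp2), 3)
  expect_equal(sp2$x, c(1, 2, 4))

  # generator output survives a write/read round trip
  coh <- generate_cohort(small_config(seed = 11))
  sid <- names(coh$spots)[1]
  orig <- coh$spots[[sid]]
  write_spots(orig, f)
  back <- read_spots(f, panel)
  back$sample_id <- orig$sample_id
  expect_equal(back$gene, orig$gene)
  expect_equal(back$cell_id, orig$cell_id)
  expect_equal(back$x, orig$x, tolerance = 1e-12)

  # error contracts
  write.csv(df[, c("gene", "x", "y")], f, row.names = FALSE)
  expect_error(read_spots(f, panel), "missing required column")
  writeLines("gene,x,y,cell_id", f)
  expect_error(read_spots(f, panel), "empty")
})

test_that("build_cell_matrix counts spots and averages centroids", {
  spots <- tibble::tibble(
    gene = c("Mbp", "Mbp", "App", "Plp1"),
    x = c(0, 2, 10, 11), y = c(0, 0, 5, 5),
    cell_id = c(7, 7, 7, 9), sample_id = "s1")
  meta <- tibble::tibble(sample_id = "s1", subject_id = "m1",
                         group = "C-NB", hemisphere = "L")
  cm <- build_cell_matrix(spots, meta)
  expect_equal(unname(cm$counts["Mbp", "7"]), 2)
  expect_equal(unname(cm$counts["App", "7"]), 1)
  expect_equal(unname(cm$counts["Plp1", "9"]), 1)
  expect_equal(sum(cm$counts), 4)
  c7 <- cm$cells[cm$cells$cell_id == "7", ]
  expect_equal(c7$x, mean(c(0, 2, 10)))

  # centroid of two spots at (0,0) and (2,0) is (1,0)
  sp2 <- tibble::tibble(gene = c("Mbp", "Mbp"), x = c(0, 2), y = c(0, 0),
                        cell_id = 1, sample_id = "s1")
  cm2 <- build_cell_matrix(sp2, meta)
  expect_equal(cm2$cells$x, 1)
  expect_equal(cm2$cells$y, 0)

  # unassigned spots excluded and counted; all-unassigned errors
  sp3 <- sp2
  sp3$cell_id[1] <- NA
  cm3 <- build_cell_matrix(sp3, meta)
  expect_equal(cm3$unassigned_spots, 1L)
  expect_equal(sum(cm3$counts), 1)
  sp3$cell_id <- NA
  expect_error(build_cell_matrix(sp3, meta), "no spots")
})

test_that("generator bookkeeping: cell matrix recovers per-cell spot counts", {
  coh <- generate_cohort(small_config(seed = 3))
  sid <- names(coh$spots)[5]
  spots <- coh$spots[[sid]]
  meta <- coh$metadata[coh$metadata$sample_id == sid, ]
  cm <- build_cell_matrix(spots, meta)
  # oracle: direct tabulation of the emitted spot table
  tab <- table(spots$gene, spots$cell_id)
  expect_equal(sum(cm$counts), nrow(spots))
  for (g in sample(rownames(tab), 20)) {
    for (cid in sample(colnames(tab), 5)) {
      expect_equal(unname(cm$counts[g, cid]), unname(tab[g, cid]))
    }
  }
})

test_that("region assignment: containment, none, SGL flag, tie-break", {
  polys <- list(s1 = list(DG = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                          SGL = cbind(c(0, 10, 10, 0), c(7, 7, 10, 10)),
                          CA1 = cbind(c(20, 30, 30, 20), c(0, 0, 10, 10))))
  masks <- region_masks(polys)
  counts <- matrix(0L, nrow = 2, ncol = 4,
                   dimnames = list(c("App", "Mbp"), as.character(1:4)))
  cm <- dense_cell_matrix(counts, x = c(5, 50, 25, 5), y = c(2, 50, 5, 8),
                          region = NA_character_)
  cm <- assign_regions(cm, masks)
  expect_equal(cm$cells$region, c("DG", "none", "CA1", "DG"))
  expect_equal(cm$cells$in_sgl, c(FALSE, FALSE, FALSE, TRUE))

  # idempotent and order-independent
  cm2 <- assign_regions(cm, masks)
  expect_identical(cm$cells$region, cm2$cells$region)
  perm <- c(3, 1, 4, 2)
  cmp <- dense_cell_matrix(counts[, perm, drop = FALSE],
                           x = c(5, 50, 25, 5)[perm],
                           y = c(2, 50, 5, 8)[perm])
  cmp <- assign_regions(cmp, masks)
  expect_equal(cmp$cells$region, cm$cells$region[perm])

  # smallest-area polygon wins on overlap, with a warning
  polys2 <- list(s1 = list(CA1 = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                           CA2 = cbind(c(4, 6, 6, 4), c(4, 4, 6, 6))))
  masks2 <- region_masks(polys2)
  cmo <- dense_cell_matrix(counts[, 1, drop = FALSE], x = 5, y = 5)
  expect_warning(cmo <- assign_regions(cmo, masks2), "multiple")
  expect_equal(cmo$cells$region, "CA2")
})

test_that("uniform points hit a square mask in proportion to its area", {
  set.seed(42)
  n <- 1000
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  polys <- list(s1 = list(DG = cbind(c(20, 70, 70, 20), c(20, 20, 70, 70))))
  counts <- matrix(0L, 1, n, dimnames = list("App", as.character(1:n)))
  cm <- dense_cell_matrix(counts, x = x, y = y)
  cm <- assign_regions(cm, region_masks(polys))
  frac <- mean(cm$cells$region == "DG")
  expected <- 0.25
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 4 * se)
})

test_that("point-in-polygon agrees with a ray-casting oracle", {
  set.seed(7)
  for (rep in 1:200) {
    poly <- random_polygon(sample(4:10, 1))
    x <- runif(5, -1.2, 1.2); y <- runif(5, -1.2, 1.2)
    got <- point_in_polygon(x, y, poly)
    want <- oracle_point_in_polygon(x, y, poly)
    expect_identical(got, want)
  }
  # boundary counts as inside
  expect_true(point_in_polygon(0.5, 0, unit_square))
  expect_true(point_in_polygon(0, 0, unit_square))
})

test_that("concat_samples binds columns, conserves totals, checks panels", {
  coh <- generate_cohort(small_config(seed = 5))
  mats <- lapply(names(coh$spots)[1:2], function(sid) {
    build_cell_matrix(coh$spots[[sid]],
                      coh$metadata[coh$metadata$sample_id == sid, ])
  })
  both <- concat_samples(mats)
  expect_equal(ncol(both$counts), ncol(mats[[1]]$counts) + ncol(mats[[2]]$counts))
  expect_equal(sum(both$counts), sum(mats[[1]]$counts) + sum(mats[[2]]$counts))
  expect_true(all(grepl(":", both$cells$cell_id)))

  # single-matrix concat is the identity up to id prefixing
  one <- concat_samples(mats[1])
  expect_equal(sum(one$counts), sum(mats[[1]]$counts))
  expect_equal(unname(as.matrix(one$counts)), unname(as.matrix(mats[[1]]$counts)))

  # mismatched panels rejected
  bad <- mats[[2]]
  bad$counts <- bad$counts[rev(seq_len(nrow(bad$counts))), ]
  expect_error(concat_samples(list(mats[[1]], bad)), "mismatch")
})

test_that("spot conservation: assigned + unassigned + dropped = input rows", {
  panel <- gene_panel()
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(gene = c("Mbp", "Fake1", "App", "Cck", "Fake2"),
                   x = 1:5, y = 1:5, cell_id = c(1, 1, NA, 2, 2))
  write.csv(df, f, row.names = FALSE)
  sp <- suppressMessages(read_spots(f, panel, sample_id = "s1"))
  meta <- tibble::tibble(sample_id = "s1", subject_id = "m1",
                         group = "C-NB", hemisphere = "L")
  cm <- build_cell_matrix(sp, meta)
  expect_equal(sum(cm$counts) + cm$unassigned_spots +
                 attr(sp, "dropped_off_panel"), nrow(df))
})

test_that("masks round-trip through JSON and areas use the shoelace formula", {
  polys <- list(s1 = list(DG = cbind(c(0, 1000, 1000, 0), c(0, 0, 2000, 2000))))
  masks <- region_masks(polys)
  expect_equal(masks$area_mm2, 2)  # 1000 x 2000 um^2 = 2 mm^2
  f <- withr::local_tempfile(fileext = ".json")
  write_masks(masks, f)
  back <- read_masks(f)
  expect_equal(back$area_mm2, masks$area_mm2)
  expect_equal(back$vertices[[1]], unname(masks$vertices[[1]]))

  # triangle area, and self-intersecting polygons rejected
  expect_equal(polygon_area(cbind(c(0, 4, 0), c(0, 0, 3))), 6)
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(region_masks(list(s = list(R = bowtie))), "self-intersecting")
})
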