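test_that("default template has exactly 1366 cells in 7 labelled layers", {
  g <- test_graph()
  expect_equal(g$n, 1366L)
  expect_equal(nrow(g$cells), 1366L)
  expect_equal(sort(unique(g$cells$layer)), 1:7)
  expect_setequal(unique(g$cells$label), c("L1", "L2", "L3", "deeper"))
  # layer labels partition the cells
  expect_equal(sum(table(g$cells$layer)), 1366L)
  # L1 cells have no neighbour shallower than themselves
  l1 <- g$cells$id[g$cells$layer == 1]
  nb_z <- g$cells$z[g$edges$j[g$edges$i %in% l1]]
  expect_true(all(nb_z >= min(g$cells$z)))
})

test_that("edge set is symmetric with identical area and distance", {
  g <- test_graph()
  e <- g$edges
  key <- paste(e$i, e$j)
  rev_key <- paste(e$j, e$i)
  expect_true(all(rev_key %in% key))
  m <- match(rev_key, key)
  expect_equal(e$area, e$area[m])
  expect_equal(e$distance, e$distance[m])
  expect_true(all(e$area > 0))
  expect_true(all(e$distance > 0))
})

test_that("minimal one-cell-per-layer stack gives 3 cells, 2 contacts, L1-L3", {
  g <- stack_graph()
  expect_equal(g$n, 3L)
  expect_equal(nrow(g$edges), 4L)  # 2 contacts, both directions
  expect_equal(g$cells$label, c("L1", "L2", "L3"))
})

test_that("builder validates its inputs", {
  expect_error(build_sam_template(cell_radius = -1), "positive")
  expect_error(build_sam_template(n_layers = 2), "n_layers")
  expect_error(build_sam_template(n_layers = 4, layer_radii = c(3, 2, 2, 2),
                                  cell_radius = 0.25), "non-decreasing")
  # layers too far apart to touch: disconnected
  expect_error(build_sam_template(n_layers = 3, layer_radii = rep(2, 3),
                                  cell_radius = 0.25, neighbor_factor = 0.5))
})

test_that("interior cells have at least 3 neighbours", {
  g <- test_graph()
  deg <- tabulate(g$edges$i, nbins = g$n)
  interior <- g$cells$layer %in% 2:6 &
    sqrt(g$cells$x^2 + g$cells$y^2) <
      (g$meta$layer_radii[g$cells$layer] - 2 * g$meta$cell_radius)
  expect_true(all(deg[interior] >= 3))
})

test_that("synthesis indicator respects radius, depth window and closed boundary", {
  g <- test_graph()
  cells <- g$cells
  ind <- wus_synthesis_indicator(g, r_w = 1.5, L_w = 2.5)
  expect_true(all(ind[cells$x^2 + cells$y^2 > 1.5^2] == 0))
  on_axis <- which(cells$x^2 + cells$y^2 <= 1.5^2 & cells$z <= 2.5)
  expect_true(all(ind[on_axis] == 1))
  # closed upper boundary: a synthetic cell exactly at the boundary is inside
  boundary <- data.frame(x = 1.5, y = 0, z = 2.5)
  expect_equal(wus_synthesis_indicator(boundary, r_w = 1.5, L_w = 2.5), 1L)
  expect_error(wus_synthesis_indicator(g, r_w = -1, L_w = 1), "positive")
})

test_that("the shipped synthesis domain is a subset of L2-and-deeper", {
  g <- test_graph()
  p <- calibrated_params()
  ind <- wus_synthesis_indicator(g, p$r_w, p$L_w, p$L_w_min)
  expect_true(sum(ind) > 0)
  expect_true(all(g$cells$layer[ind == 1] >= 2))
})

test_that("apex selection returns the nearest-axis cells per layer", {
  g <- test_graph()
  a3 <- apex_cells(g, 3)
  expect_equal(nrow(a3), 3 * 7)
  expect_true(all(table(a3$layer) == 3))
  expect_true(all(g$cells$apex[a3$id]))
  # width-5 selection is symmetric about the axis (mean position near 0)
  a5 <- apex_cells(g, 5)
  for (l in 1:7) {
    ids <- a5$id[a5$layer == l]
    expect_lt(abs(mean(g$cells$x[ids])) + abs(mean(g$cells$y[ids])), 0.5)
  }
  # selected L1 cells are strictly shallower than selected L3 cells
  expect_true(max(g$cells$z[a3$id[a3$layer == 1]]) <
              min(g$cells$z[a3$id[a3$layer == 3]]))
  expect_error(apex_cells(g, 2), "width")
  expect_error(apex_cells(g, 6), "width")
})

test_that("csv round trip preserves the graph", {
  g <- mini_graph()
  prefix <- file.path(tempdir(), "graph_rt")
  write_cellgraph(g, prefix)
  g2 <- read_cellgraph(prefix)
  expect_equal(g2$n, g$n)
  expect_equal(g2$cells$x, g$cells$x, tolerance = 1e-12)
  expect_equal(g2$edges$distance, g$edges$distance, tolerance = 1e-12)
  expect_equal(as.matrix(g2$G), as.matrix(g$G), tolerance = 1e-12)
})
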