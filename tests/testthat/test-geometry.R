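test_that("clustered design geometry matches its specification", {
  d <- make_clustered_design(9, 3, 3, 3.5, cluster_dx_km = 28,
                             cluster_dy_km = c(36, 45))
  expect_equal(nrow(d$coords), 81L)
  # within-cluster nearest-neighbour distance equals the cell spacing
  nn <- apply(as.matrix(dist(d$coords[1:9, ])), 1,
              function(r) min(r[r > 0]))
  expect_equal(unname(nn), rep(3.5, 9))
  # cell and cluster coverage
  expect_equal(3.5^2, 12.25)
  expect_equal(9 * 3.5^2, 110.25)

  # degenerate single-detector design sits at the cluster centre
  d1 <- make_clustered_design(1, 1, 1, 2)
  expect_equal(nrow(d1$coords), 1L)
  expect_equal(unname(d1$coords[1, ]), c(0, 0))

  # two 2x2 clusters, 4 km cells, 20 km apart: nearest inter-cluster gap
  d2 <- make_clustered_design(2, 2, 2, 4, cluster_dx_km = 20)
  expect_equal(nrow(d2$coords), 8L)
  g <- as.matrix(dist(d2$coords))
  inter <- g[1:4, 5:8]
  expect_equal(min(inter), 20 - 4)

  expect_error(make_clustered_design(9, 3, 3, -1), "positive")

  # dropout mask reproduces a partially realized array
  d3 <- make_clustered_design(9, 3, 3, 3.5, dropout = 1:13)
  expect_equal(nrow(d3$coords), 68L)
})

test_that("state space buffers the joint extent and area is translation invariant", {
  one <- trap_array(rbind(c(0, 0)), "camera")
  ss <- make_state_space(one, buffer_km = 25)
  expect_equal(ss$area, 2500)
  expect_equal(c(ss$xmax - ss$xmin, ss$ymax - ss$ymin), c(50, 50))

  d <- make_clustered_design(4, 3, 3, 3.5)
  ss1 <- make_state_space(d, buffer_km = 25)
  d$coords <- d$coords + 1234.5
  ss2 <- make_state_space(d, buffer_km = 25)
  expect_equal(ss1$area, ss2$area)

  # combining arrays takes the joint extent
  a <- trap_array(rbind(c(0, 0)), "camera")
  b <- trap_array(rbind(c(10, 0)), "live")
  expect_equal(make_state_space(a, b, buffer_km = 5)$area, 20 * 10)

  expect_error(make_state_space(buffer_km = 5), "at least one")
  expect_error(make_state_space(a, buffer_km = -1), "positive")
})

test_that("exposure matrices honour operation schedules, deaths and markings", {
  live_op <- matrix(c(10, 30), 2, 1)       # two live traps, days of effort
  cam_op <- matrix(1, 3, 17)               # three cameras, 17 occasions
  ex <- build_exposure(live_op, cam_op, n_marked = 3)
  expect_equal(dim(ex$E_R), c(3L, 3L))
  expect_true(all(ex$E_R == 17))
  expect_equal(ex$E_M[1, ], c(10, 30))
  expect_true(all(ex$m == 1L))

  # death before occasion 1: zero resighting exposure, all-dead status row
  ev <- data.frame(individual = 2L, occasion = 1L, event = "died")
  ex2 <- build_exposure(live_op, cam_op, 3, events = ev)
  expect_equal(unname(ex2$E_R[2, ]), c(0, 0, 0))
  expect_true(all(ex2$m[2, ] == 2L))
  expect_equal(unname(ex2$E_M[2, ]), c(10, 30))  # marking preceded resighting

  # marked mid-survey at occasion 5 of 17
  ev3 <- data.frame(individual = 1L, occasion = 5L, event = "marked")
  ex3 <- build_exposure(live_op, cam_op, 3, events = ev3)
  expect_equal(unname(ex3$m[1, ]), c(rep(0L, 4), rep(1L, 13)))
  expect_true(all(ex3$E_R[1, ] == 17))           # alive throughout

  # death is absorbing after a mid-survey death
  ev4 <- data.frame(individual = c(1L, 1L), occasion = c(3L, 9L),
                    event = c("marked", "died"))
  ex4 <- build_exposure(live_op, cam_op, 3, events = ev4)
  expect_equal(unname(ex4$m[1, ]), c(0L, 0L, rep(1L, 6), rep(2L, 9)))
  expect_true(all(ex4$E_R[1, ] == 8))

  # inconsistent chronology
  bad <- data.frame(individual = c(1L, 1L), occasion = c(9L, 3L),
                    event = c("marked", "died"))
  expect_error(build_exposure(live_op, cam_op, 3, events = bad), "dead before")

  # zeroing an occasion weakly decreases every resighting exposure entry
  cam_op2 <- cam_op; cam_op2[, 8] <- 0
  ex5 <- build_exposure(live_op, cam_op2, 3, events = ev4)
  expect_true(all(ex5$E_R <= ex4$E_R))
})
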