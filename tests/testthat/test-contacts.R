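two_residue_structure <- function(d) {
  atoms <- tibble::tibble(
    element = "C", name = "CA", residue_id = c(1L, 1L),
    residue_name = "GLY", chain_id = c("A", "B"),
    radius = 1.7, mass = 12.011)
  hc_structure(atoms, list(rbind(c(0, 0, 0), c(d, 0, 0))))
}

test_that("the contact criterion is strictly below the cutoff", {
  st <- two_residue_structure(4.9)
  hits <- frame_contacts(st, 1, residue_selection("A"), residue_selection("B"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distance, 4.9, tolerance = 1e-9)
  # exactly at the cutoff: no contact
  st5 <- two_residue_structure(5.0)
  expect_equal(nrow(frame_contacts(st5, 1, residue_selection("A"),
                                   residue_selection("B"))), 0L)
  expect_error(frame_contacts(st5, 1, residue_selection(c("A", "B")),
                              residue_selection("B")), "overlap")
})

test_that("contacts on a synthetic residue grid equal the brute-force all-pairs scan", {
  set.seed(19)
  na <- 10; nb <- 10
  xa <- matrix(stats::runif(3 * na, 0, 20), ncol = 3)
  xb <- matrix(stats::runif(3 * nb, 0, 20), ncol = 3)
  atoms <- tibble::tibble(
    element = "C", name = "CA",
    residue_id = c(seq_len(na), seq_len(nb)),
    residue_name = "GLY",
    chain_id = rep(c("A", "B"), c(na, nb)),
    radius = 1.7, mass = 12.011)
  st <- hc_structure(atoms, list(rbind(xa, xb)))
  hits <- frame_contacts(st, 1, residue_selection("A"), residue_selection("B"),
                         cutoff = 6)
  brute <- NULL
  for (i in seq_len(na)) for (j in seq_len(nb))
    if (sqrt(sum((xa[i, ] - xb[j, ])^2)) < 6)
      brute <- rbind(brute, c(i, j))
  expect_equal(nrow(hits), nrow(brute))
  got <- paste(hits$residue_a, hits$residue_b)
  expect_setequal(got, paste(brute[, 1], brute[, 2]))
})

test_that("persistence filtering is strict at the threshold", {
  traj <- synth_trajectory(c(1.0, 0.91, 0.89), n_frames = 100, seed = 3)
  pc <- persistent_contacts(traj, residue_selection("A"),
                            residue_selection("B"), threshold = 0.90)
  expect_equal(pc$residue_a, c(1L, 2L))       # 0.89 dropped, 0.91 kept
  expect_equal(pc$persistence, c(1.0, 0.91))
  # threshold 0: every pair ever in contact; threshold 1: all-frame only
  pc0 <- persistent_contacts(traj, residue_selection("A"),
                             residue_selection("B"), threshold = 0)
  expect_equal(nrow(pc0), 3L)
  pc1 <- persistent_contacts(traj, residue_selection("A"),
                             residue_selection("B"), threshold = 1)
  expect_equal(nrow(pc1), 0L)                 # strict: fraction must exceed 1
})

test_that("scheduled persistence fractions are recovered exactly", {
  sched <- c(1.0, 0.95, 0.9, 0.89, 0.53, 0.07)
  traj <- synth_trajectory(sched, n_frames = 100, seed = 3)
  pc <- persistent_contacts(traj, residue_selection("A"),
                            residue_selection("B"), threshold = 0)
  expect_equal(pc$persistence[order(pc$residue_a)],
               sched[sched > 0])
})

test_that("map comparison partitions pairs by identity", {
  mk <- function(res_a) tibble::tibble(chain_a = "A", residue_a = res_a,
                                       chain_b = "B", residue_b = res_a,
                                       persistence = 1)
  a <- mk(c(1L, 2L, 3L)); b <- mk(c(2L, 3L, 4L))
  cmp <- compare_maps(a, b)
  expect_equal(cmp$shared$residue_a, c(2L, 3L))
  expect_equal(cmp$only_a$residue_a, 1L)
  expect_equal(cmp$only_b$residue_a, 4L)
  same <- compare_maps(a, a)
  expect_equal(nrow(same$only_a), 0L)
  expect_equal(nrow(same$only_b), 0L)
  disj <- compare_maps(mk(1L), mk(2L))
  expect_equal(nrow(disj$shared), 0L)

  # randomized pair sets against brute-force set algebra
  set.seed(5)
  ra <- sample.int(50, 20); rb <- sample.int(50, 20)
  cmp2 <- compare_maps(mk(sort(ra)), mk(sort(rb)))
  expect_setequal(cmp2$shared$residue_a, intersect(ra, rb))
  expect_setequal(cmp2$only_a$residue_a, setdiff(ra, rb))
  expect_setequal(cmp2$only_b$residue_a, setdiff(rb, ra))
})

test_that("contact symmetry: swapping the selections transposes the map", {
  traj <- synth_trajectory(c(1.0, 0.95), n_frames = 10, seed = 8)
  ab <- frame_contacts(traj, 1, residue_selection("A"), residue_selection("B"))
  ba <- frame_contacts(traj, 1, residue_selection("B"), residue_selection("A"))
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$residue_a, ab$residue_b),
                  paste(ba$residue_b, ba$residue_a))
})
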