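test_that("generation is a pure function of params and seed", {
  p <- phantom_params()
  a <- generate_case(p, "PD", seed = 12)
  b <- generate_case(p, "PD", seed = 12)
  expect_identical(a$echoes$volumes, b$echoes$volumes)
  expect_identical(a$snpc_mask, b$snpc_mask)
  expect_identical(a$rater2_mask, b$rater2_mask)
})

test_that("echo magnitudes decay with TE before noise", {
  p <- phantom_params(noise_sigma = 0)
  cs <- generate_case(p, "HC", seed = 3)
  means <- vapply(cs$echoes$volumes, function(v) mean(v[cs$snpc_mask]),
                  numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("PD attenuates the swallow-tail intensity", {
  p <- phantom_params(noise_sigma = 0)
  hc <- generate_case(p, "HC", seed = 5)
  pd <- generate_case(p, "PD", seed = 5)
  m_hc <- mean(hc$echoes$volumes[[1]][hc$swallowtail_mask])
  m_pd <- mean(pd$echoes$volumes[[1]][pd$swallowtail_mask])
  expect_lt(m_pd, m_hc)
})

test_that("PD shrinks the hyperintense SNpc area (100-case count)", {
  p <- phantom_params(noise_sigma = 0)
  area <- function(label, seed) {
    cs <- generate_case(p, label, seed = seed)
    v <- cs$echoes$volumes[[1]]
    vals <- v[cs$snpc_mask]
    sum(vals > (min(vals) + max(vals)) / 2)
  }
  a_hc <- vapply(1:50, function(s) area("HC", s), numeric(1))
  a_pd <- vapply(51:100, function(s) area("PD", s), numeric(1))
  expect_lt(mean(a_pd), mean(a_hc))
  # the mask itself also shrinks by construction
  n_hc <- vapply(1:20, function(s) sum(generate_case(p, "HC", s)$snpc_mask),
                 numeric(1))
  n_pd <- vapply(1:20, function(s) sum(generate_case(p, "PD", s)$snpc_mask),
                 numeric(1))
  expect_lt(mean(n_pd), mean(n_hc))
})

test_that("masks are bilateral and span exactly 4 contiguous slices", {
  p <- phantom_params()
  for (s in c(1, 9, 33)) {
    cs <- generate_case(p, sample(c("HC", "PD"), 1), seed = s)
    zs <- which(apply(cs$snpc_mask, 3, any))
    expect_length(zs, 4L)
    expect_true(all(diff(zs) == 1L))
    for (z in zs) {
      expect_identical(count_components_2d(cs$snpc_mask[, , z]), 2L)
    }
    expect_identical(dim(cs$snpc_mask), dim(cs$echoes$volumes[[1]]))
  }
})

test_that("cohort generation matches requested sizes and is reproducible", {
  expect_length(generate_cohort(0, 0, seed = 1), 0L)
  p <- phantom_params()
  co <- generate_cohort(5, 7, p, seed = 9)
  expect_length(co, 12L)
  labs <- vapply(co, `[[`, "", "label")
  expect_identical(sum(labs == "PD"), 7L)
  ids <- vapply(co, `[[`, "", "case_id")
  expect_identical(anyDuplicated(ids), 0L)
  co2 <- generate_cohort(5, 7, p, seed = 9)
  expect_identical(ids, vapply(co2, `[[`, "", "case_id"))
  expect_identical(labs, vapply(co2, `[[`, "", "label"))
})

test_that("mask perturbation gives realistic inter-rater variation", {
  p <- phantom_params()
  cs <- generate_case(p, "HC", seed = 2)
  expect_identical(perturb_mask(cs$snpc_mask, seed = 1, flip_prob = 0),
                   cs$snpc_mask)
  expect_identical(dice(cs$snpc_mask, cs$snpc_mask), 1)
  dscs <- counts <- numeric(30)
  for (s in 1:30) {
    m2 <- perturb_mask(cs$snpc_mask, seed = s)
    dscs[s] <- dice(cs$snpc_mask, m2)
    counts[s] <- sum(m2) / sum(cs$snpc_mask)
  }
  expect_gte(mean(dscs), 0.85)
  expect_lte(mean(dscs), 0.98)
  expect_true(all(counts > 0.7 & counts < 1.3))
  expect_error(perturb_mask(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("noiseless classes separate on mean swallow-tail intensity", {
  p <- phantom_params(noise_sigma = 0)  # attenuation 0.5, shrink 0.8 defaults
  tail_mean <- function(label, seed) {
    cs <- generate_case(p, label, seed = seed)
    mean(reconstruct_setmag(cs$echoes)$intensity[cs$swallowtail_mask])
  }
  m_hc <- vapply(1:25, function(s) tail_mean("HC", s), numeric(1))
  m_pd <- vapply(101:125, function(s) tail_mean("PD", s), numeric(1))
  thr <- (mean(m_hc) + mean(m_pd)) / 2
  acc <- (sum(m_hc > thr) + sum(m_pd < thr)) / 50
  expect_gte(acc, 0.9)
})

test_that("invalid phantom geometry and parameters are rejected", {
  expect_error(phantom_params(echo_times = c(10, 5, 15)), "increasing")
  expect_error(phantom_params(echo_times = c(5, 10)), "3 echo")
  expect_error(phantom_params(swallowtail_attenuation_pd = 1.5), "\\[0, 1\\]")
  expect_error(phantom_params(snpc_area_shrink_pd = 0), "\\(0, 1\\]")
  expect_error(phantom_params(midbrain_center = c(5, 32, 6)), "fit")
  expect_error(phantom_params(snpc_slice_start = 11), "slices")
})
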