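test_that("query_if returns the planted bin-pair value and obeys symmetry", {
  # 60 kb chromosome at 10 kb: bins 0..5; single nonzero entry at (1, 4)
  store <- tiny_store(tibble::tibble(
    chromA = "chrT", binA = 1, chromB = "chrT", binB = 4, value = 2.5
  ))
  a <- region("chrT", 10000, 20000) # bin 1
  b <- region("chrT", 40000, 50000) # bin 4
  expect_equal(query_if(store, a, b, 10000), 2.5)
  expect_equal(query_if(store, b, a, 10000), 2.5)
  # rectangle missing the entry -> empty sum
  expect_equal(query_if(store, region("chrT", 0, 10000), b, 10000), 0)
})

test_that("query_if matches the brute-force oracle on random stores", {
  for (seed in 1:25) {
    fix <- random_store(seed)
    w <- sample(fix$resolutions, 1)
    a <- random_region(fix$chrom_sizes)
    b <- random_region(fix$chrom_sizes)
    expect_equal(
      query_if(fix$store, a, b, w),
      oracle_query_if(fix, a, b, w),
      tolerance = 1e-12
    )
    expect_equal(query_if(fix$store, a, b, w), query_if(fix$store, b, a, w))
  }
})

test_that("query_if is additive over a bin-aligned partition and monotone in region size", {
  for (seed in 26:35) {
    fix <- random_store(seed)
    w <- min(fix$resolutions)
    chrom <- names(fix$chrom_sizes)[1]
    len <- fix$chrom_sizes[[chrom]]
    a <- random_region(fix$chrom_sizes)
    whole <- region(chrom, 0, len)
    mid <- floor(len / (2 * w)) * w
    left <- region(chrom, 0, mid)
    right <- region(chrom, mid, len)
    expect_equal(
      query_if(fix$store, a, whole, w),
      query_if(fix$store, a, left, w) + query_if(fix$store, a, right, w)
    )
    # enlarging a region never decreases the sum
    small <- region(chrom, mid, min(len, mid + w))
    expect_gte(query_if(fix$store, a, whole, w), query_if(fix$store, a, small, w))
  }
})

test_that("store errors name unknown windows and chromosomes", {
  store <- tiny_store()
  a <- region("chrT", 0, 10000)
  expect_error(query_if(store, a, a, 2000), "available")
  expect_error(query_if(store, region("chrX", 0, 10), a, 10000), "chrX")
  expect_error(
    contact_store(
      list("1000" = tibble::tibble(
        chromA = "chrT", binA = 999, chromB = "chrT", binB = 0, value = 1
      )),
      c(chrT = 60000)
    ),
    "out of range"
  )
})

test_that("virtual_4c extracts the viewpoint row and satisfies the whole-chromosome identity", {
  # single nonzero row: contacts of bin 2 with bins 0..5
  vals <- c(0.5, 1, 4, 2, 0.25, 0.125)
  coo <- tibble::tibble(
    chromA = "chrT", binA = pmin(2, 0:5), chromB = "chrT", binB = pmax(2, 0:5),
    value = vals
  )
  store <- tiny_store(coo)
  vp <- region("chrT", 20000, 30000) # bin 2
  prof <- virtual_4c(store, vp, 10000)
  expect_equal(nrow(prof), 6)
  expect_equal(prof$value, vals) # row extraction, self-bin included
  expect_equal(
    sum(prof$value),
    query_if(store, vp, region("chrT", 0, 60000), 10000)
  )
  # all-zero chromosome -> all-zero profile of correct length
  empty <- tiny_store()
  prof0 <- virtual_4c(empty, vp, 10000)
  expect_equal(prof0$value, rep(0, 6))
  expect_error(virtual_4c(store, region("chrT", 70000, 80000), 10000), "beyond")
})

test_that("random virtual-4C profiles satisfy the query_if consistency identity", {
  for (seed in 36:45) {
    fix <- random_store(seed)
    w <- sample(fix$resolutions, 1)
    vp <- random_region(fix$chrom_sizes)
    prof <- virtual_4c(fix$store, vp, w)
    whole <- region(vp$chrom, 0, fix$chrom_sizes[[vp$chrom]])
    expect_equal(sum(prof$value), query_if(fix$store, vp, whole, w), tolerance = 1e-12)
  }
})

test_that("the native COO store round-trips through the manifest", {
  fix <- random_store(99)
  dir <- withr::local_tempdir()
  man <- write_contact_store(fix$store, dir)
  store2 <- read_contact_store(man)
  expect_equal(store2$resolutions, fix$store$resolutions)
  expect_equal(store2$chrom_sizes, fix$store$chrom_sizes)
  for (r in names(fix$store$maps)) {
    a <- dplyr::arrange(fix$store$maps[[r]], chromA, binA, chromB, binB)
    b <- dplyr::arrange(store2$maps[[r]], chromA, binA, chromB, binB)
    expect_equal(as.data.frame(a), as.data.frame(b))
  }
})
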