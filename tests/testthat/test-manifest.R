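test_that("default manifest carries the canonical per-hemisphere counts", {
  m <- default_loop_manifest()
  tab <- table(m$edges$loop, m$edges$hemisphere)
  for (h in c("L", "R")) {
    expect_equal(tab["short", h], 19)
    expect_equal(tab["long", h], 21)
    expect_equal(tab["short", h] + tab["long", h], 40)
    expect_equal(tab["atlas", h], 26)
  }
  expect_silent(validate_loop_manifest(m))
})

test_that("shipped manifest TSV loads, validates, and matches the builder", {
  m <- load_loop_manifest()
  d <- default_loop_manifest()
  cols <- c("loop", "hemisphere", "region_a", "region_b")
  expect_equal(m$edges[cols], d$edges[cols])
  expect_match(m$provenance, "md5")
})

test_that("manifest reconstruction contains the reported loop edges", {
  # the group-difference and prediction analyses name specific
  # subdivision-cortex connections and the loop each sits in
  e <- default_loop_manifest()$edges
  key <- edge_key(e$loop, e$hemisphere, e$region_a, e$region_b)
  expect_true(edge_key("short", "R", "CAU_M1", "M1") %in% key)
  expect_true(edge_key("short", "R", "PUT_M1", "M1") %in% key)
  expect_true(edge_key("short", "R", "PUT_DLPFC", "DLPFC") %in% key)
  expect_true(edge_key("short", "L", "CAU_MPFC", "MPFC") %in% key)
  expect_true(edge_key("long", "R", "THA_DLPFC", "DLPFC") %in% key)
  expect_true(edge_key("long", "R", "CAU_M1", "M1") %in% key)
  expect_true(edge_key("long", "R", "PUT_M1", "M1") %in% key)
})

test_that("atlas enumeration yields the 26 expected pairs per hemisphere", {
  for (h in c("L", "R")) {
    a <- enumerate_atlas_edges(h)
    expect_equal(nrow(a), 26)
    expect_equal(sum(a$region_a %in% c("MPFC", "DLPFC", "M1", "PMC", "OFC")),
                 20)
    pairs <- paste(pmin(a$region_a, a$region_b),
                   pmax(a$region_a, a$region_b))
    expect_false(any(duplicated(pairs)))
    # no cortical-cortical pairs
    cort <- c("MPFC", "DLPFC", "M1", "PMC", "OFC")
    expect_false(any(a$region_a %in% cort & a$region_b %in% cort))
    expect_true(paste("CAU", "M1") %in% paste(pmin(a$region_b, a$region_a),
                                              pmax(a$region_b, a$region_a)) ||
                any(a$region_a == "M1" & a$region_b == "CAU"))
    expect_true(any((a$region_a == "CAU" & a$region_b == "THA") |
                    (a$region_a == "THA" & a$region_b == "CAU")))
  }
  l <- enumerate_atlas_edges("L")
  r <- enumerate_atlas_edges("R")
  l$hemisphere <- "R"
  expect_equal(l, r)
})

test_that("manifest validation names the violated count", {
  m <- default_loop_manifest()
  drop <- which(m$edges$loop == "short" & m$edges$hemisphere == "R")[1L]
  bad <- m
  bad$edges <- bad$edges[-drop, ]
  expect_error(validate_loop_manifest(bad), "short, R: 18 != 19")
})

test_that("manifest validation rejects duplicates, self-pairs and unknowns", {
  m <- default_loop_manifest()
  dup <- m
  row <- dup$edges[dup$edges$loop == "short" & dup$edges$hemisphere == "L", ][1L, ]
  # re-add the same unordered pair reversed
  row2 <- row
  row2$region_a <- row$region_b
  row2$region_b <- row$region_a
  dup$edges <- rbind(dup$edges, row2)
  expect_error(validate_loop_manifest(dup), "duplicated unordered pair")

  self <- m
  self$edges$region_b[1L] <- self$edges$region_a[1L]
  expect_error(validate_loop_manifest(self), "self-pair")

  unk <- m
  unk$edges$region_a[1L] <- "NOPE"
  expect_error(validate_loop_manifest(unk), "unresolvable region")
})

test_that("malformed manifest files fail with the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("loop\themisphere\tregion_a\tregion_b",
               "short\tL\tM1\tCAU_M1",
               "short\tL\tM1"), f)
  expect_error(load_loop_manifest(f), "line 3")
  expect_error(load_loop_manifest(file.path(tempdir(), "absent.tsv")),
               "not found")
})

test_that("a round-tripped manifest survives write/load", {
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- default_loop_manifest()
  write_loop_manifest(m, f)
  m2 <- load_loop_manifest(f)
  cols <- c("loop", "hemisphere", "region_a", "region_b")
  expect_equal(m$edges[cols], m2$edges[cols])
})

test_that("region table enumerates cortical, subcortical and subdivisions", {
  r <- cbtc_regions()
  expect_equal(nrow(r), 2 * (5 + 4 + 20))
  expect_false(any(duplicated(paste(r$hemisphere, r$name))))
  div <- r[r$kind == "subdivision", ]
  expect_true(all(div$parent %in% c("CAU", "PUT", "PAL", "THA")))
  expect_true(all(div$tag %in% c("MPFC", "DLPFC", "M1", "PMC", "OFC")))
  expect_equal(div$name, paste(div$parent, div$tag, sep = "_"))
})
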