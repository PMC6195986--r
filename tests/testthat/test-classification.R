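test_that("all printed case-series codes parse and re-encode canonically", {
  codes <- example_codes()
  canonical <- c("03-01-00-00", "00-00-33-33", "00-00-33-33", "00-00-33-33",
                 "00-00-3-3", "00-00-33-33", "03-03-03-03", "22-33-33-33",
                 "33-33-33-33", "33-33-33-33")
  for (i in seq_len(nrow(codes))) {
    parsed <- parse_cleft_code(codes$code[i]) # mixed en-dash/hyphen as printed
    expect_identical(encode_cleft_code(parsed), canonical[i])
  }
})

test_that("midline and paired groups are distinguished structurally", {
  midline <- parse_cleft_code("00-00-3-3")
  expect_length(midline$hard_palate, 1)
  expect_identical(midline$hard_palate, 3L)
  paired <- parse_cleft_code("00-00-33-33")
  expect_identical(paired$hard_palate, c(3L, 3L))
  # encode examples
  expect_identical(encode_cleft_code(cleft_code(c(0, 3), c(0, 1), c(0, 0), c(0, 0))),
                   "03-01-00-00")
  expect_identical(encode_cleft_code(cleft_code(c(0, 0), c(0, 0), 3, 3)),
                   "00-00-3-3")
  expect_identical(encode_cleft_code(cleft_code()), "00-00-00-00")
})

test_that("parse(encode(c)) is the identity over random valid codes", {
  set.seed(11)
  for (k in 1:1000) {
    regions <- lapply(1:4, function(i) {
      if (stats::runif(1) < 0.2) sample(0:3, 1) else sample(0:3, 2, replace = TRUE)
    })
    code <- cleft_code(regions[[1]], regions[[2]], regions[[3]], regions[[4]])
    expect_identical(parse_cleft_code(encode_cleft_code(code)), code)
  }
})

test_that("encoding is injective over paired codes", {
  set.seed(12)
  grades <- replicate(300, sample(0:3, 8, replace = TRUE), simplify = FALSE)
  grades <- unique(grades)
  encoded <- vapply(grades, function(g) {
    encode_cleft_code(cleft_code(g[1:2], g[3:4], g[5:6], g[7:8]))
  }, character(1))
  expect_equal(anyDuplicated(encoded), 0)
})

test_that("malformed codes fail with positional information", {
  expect_error(parse_cleft_code("00-00-33"), class = "cleftmorph_parse_error")
  expect_error(parse_cleft_code("00-00-33-33-00"), class = "cleftmorph_parse_error")
  expect_error(parse_cleft_code("0a-00-33-33"), class = "cleftmorph_parse_error")
  expect_error(parse_cleft_code("00-00-34-33"), class = "cleftmorph_parse_error")
  expect_error(parse_cleft_code("00-00-333-33"), class = "cleftmorph_parse_error")
  err <- tryCatch(parse_cleft_code("00-09-33-33"), error = function(e) conditionMessage(e))
  expect_match(err, "group 2")
  expect_error(cleft_code(c(0, 4)), class = "cleftmorph_validation_error")
})
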