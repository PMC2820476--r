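test_that("token and plain parsing produce the expected signed strings", {
  s <- signedString("+b -c -a +d")
  expect_equal(length(s), 4L)
  expect_equal(symbols(s), c("b", "c", "a", "d"))
  expect_equal(signs(s), c(1L, -1L, -1L, 1L))

  p <- signedString("abcd")
  expect_equal(symbols(p), c("a", "b", "c", "d"))
  expect_true(all(signs(p) == 1L))

  ## bare tokens default to '+'
  expect_true(signedString("a -b +c") == signedString("+a -b +c"))
  expect_equal(length(signedString("")), 0L)
})

test_that("malformed tokens are rejected with their position", {
  expect_error(signedString("+a -bc"), "position 2")
  expect_error(signedString("+a - b", format = "tokens"), "malformed")
})

test_that("inversion reverses order and flips signs, and is an involution", {
  expect_true(invert(signedString("+b -c -a +d")) ==
                signedString("-d +a +c -b"))
  expect_equal(length(invert(emptySignedString())), 0L)

  set.seed(11)
  for (k in seq_len(1000)) {
    s <- randomSignedString(sample(0:8, 1L), letters[1:4], signFlipProb = 0.5)
    expect_true(invert(invert(s)) == s)
  }
})

test_that("in-place substring inversion matches the signed-string algebra", {
  x <- signedString("+a +b +c +d +e +f")
  expect_true(subInvert(x, 3, 5) == signedString("+a +b -e -d -c +f"))
  ## identity span
  expect_true(subInvert(x, NA, NA) == x)
  ## whole-string in-place inversion equals invert()
  expect_true(subInvert(x, 1, 6) == invert(x))
})

test_that("substring extraction and concatenation behave like strings", {
  s <- signedString("+a -b +c")
  expect_true(s[2:3] == signedString("-b +c"))
  expect_true(c(s[1], s[2:3]) == s)
  expect_equal(as.character(signedString("abc")), "abc")
  expect_equal(as.character(s), "+a -b +c")
})

test_that("readSignedString handles tokens, plain and FASTA inputs", {
  tf <- withr::local_tempfile(lines = c(">s1 desc", "ab", "c", ">s2", "dd"))
  expect_equal(as.character(readSignedString(tf, "fasta")), "abc")
  expect_equal(as.character(readSignedString(tf, "fasta", id = "s2")), "dd")
  expect_error(readSignedString(tf, "fasta", id = "nope"), "not found")

  expect_true(readSignedString("+b -c -a +d", "tokens") ==
                signedString("+b -c -a +d"))
  expect_equal(as.character(readSignedString("abcd", "plain")), "abcd")
})
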