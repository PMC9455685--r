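test_that("the 48 disaccharide states encode to 48 distinct 11-digit codes", {
    all48 <- allDisaccharides()
    expect_length(all48, 48L)
    codes <- vapply(all48, encodeDisaccharide, character(1))
    expect_true(all(nchar(codes) == 11L))
    expect_length(unique(codes), 48L)
    expect_true(all(grepl("^[0-9]{11}$", codes)))
})

test_that("encode and decode are mutually inverse over the full state space", {
    for (d in allDisaccharides()) {
        d2 <- decodeDisaccharide(encodeDisaccharide(d))
        expect_identical(d2@epimer, d@epimer)
        expect_identical(d2@nstate, d@nstate)
        expect_identical(c(d2@s2, d2@s3, d2@s6), c(d@s2, d@s3, d@s6))
    }
})

test_that("each modification site occupies its own digit field", {
    base <- HSDisaccharide("GlcA", "NAc")
    variants <- list(
        list(d = HSDisaccharide("IdoA", "NAc"), pos = 2L),
        list(d = HSDisaccharide("GlcA", "NAc", s2 = TRUE), pos = 3L),
        list(d = HSDisaccharide("GlcA", "NS"), pos = 7L),
        list(d = HSDisaccharide("GlcA", "NAc", s3 = TRUE), pos = 8L),
        list(d = HSDisaccharide("GlcA", "NAc", s6 = TRUE), pos = 10L))
    c0 <- strsplit(encodeDisaccharide(base), "")[[1]]
    for (v in variants) {
        c1 <- strsplit(encodeDisaccharide(v$d), "")[[1]]
        expect_identical(which(c0 != c1), v$pos)
    }
})

test_that("malformed codes are rejected with the offending field named", {
    expect_error(decodeDisaccharide("11104220014"), NA) # valid baseline
    expect_error(decodeDisaccharide("1234567890"), "11 digits")
    expect_error(decodeDisaccharide("111042200104"), "11 digits")
    expect_error(decodeDisaccharide("11104220014x"), "11 digits")
    # undefined value in each variable field
    expect_error(decodeDisaccharide("13104220014"), "epimer")
    expect_error(decodeDisaccharide("12504220014"), "2-O-sulfation")
    expect_error(decodeDisaccharide("11104230014"), "N-state")
    expect_error(decodeDisaccharide("11104227014"), "3-O-sulfation")
    expect_error(decodeDisaccharide("11104220094"), "6-O-sulfation")
    # altered structural digits name their position
    expect_error(decodeDisaccharide("01104220014"), "position 1")
    expect_error(decodeDisaccharide("11104220015"), "position 11")
})

test_that("no 11-digit string outside the code image decodes", {
    image <- vapply(allDisaccharides(), encodeDisaccharide, character(1))
    set.seed(11)
    for (i in 1:200) {
        s <- paste(sample(0:9, 11, replace = TRUE), collapse = "")
        if (s %in% image) next
        expect_error(decodeDisaccharide(s))
    }
})

test_that("oligo code strings have length 11 per unit and round-trip", {
    set.seed(7)
    all48 <- allDisaccharides()
    for (i in 1:20) {
        n <- sample(1:10, 1)
        o <- HSOligo(paste0("o", i), sample(all48, n, replace = TRUE))
        code <- encodeOligo(o)
        expect_identical(nchar(code), 11L * n)
        o2 <- decodeOligo(code, oligoId(o))
        expect_identical(encodeOligo(o2), code)
        expect_identical(length(o2), n)
    }
    expect_error(decodeOligo("123"), "multiple of 11")
})

test_that("the structure dialect parses, formats and rejects unknown tokens", {
    o <- parseHSStructure("IdoA2S-GlcNS6S-GlcA-GlcNAc3S", id = "x")
    expect_identical(length(o), 2L)
    u1 <- oligoUnits(o)[[1]]
    expect_identical(u1@epimer, "IdoA")
    expect_true(u1@s2 && u1@s6 && !u1@s3)
    expect_identical(formatHSStructure(o), "IdoA2S-GlcNS6S-GlcA-GlcNAc3S")
    # en dash accepted
    o2 <- parseHSStructure("IdoA2S–GlcNS6S", id = "y")
    expect_identical(encodeOligo(o2),
                     encodeOligo(parseHSStructure("IdoA2S-GlcNS6S")))
    expect_error(parseHSStructure("XyzA-GlcNS"), "uronic-acid token")
    expect_error(parseHSStructure("GlcA-GlcNQ"), "glucosamine token")
    expect_error(parseHSStructure("GlcA"), "even number")
})

test_that("buildAlphabet sorts codes, assigns fixed letters and is order-invariant", {
    oligos <- toy_oligos()
    map <- buildAlphabet(oligos)
    # 3 distinct types across the fixture set
    expect_identical(alphabetLetters(map),
                     c("A", "C", "D", "E")[seq_along(alphabetCodes(map))])
    expect_false(is.unsorted(alphabetCodes(map), strictly = TRUE))
    # sort-then-assign oracle
    codes <- sort(unique(unlist(lapply(oligos, function(o)
        vapply(oligoUnits(o), encodeDisaccharide, character(1))))))
    expect_identical(alphabetCodes(map), codes)
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
        m2 <- buildAlphabet(oligos[perm])
        expect_identical(alphabetCodes(m2), alphabetCodes(map))
        expect_identical(alphabetLetters(m2), alphabetLetters(map))
    }
})

test_that("more than 20 distinct disaccharide types is a capacity error", {
    all48 <- allDisaccharides()
    big <- HSOligo("big", all48[1:21])
    expect_error(buildAlphabet(list(big)), "21")
    expect_silent(buildAlphabet(list(HSOligo("ok", all48[1:20]))))
})

test_that("pseudo-sequence translation preserves length, order and codes", {
    oligos <- toy_oligos()
    map <- buildAlphabet(oligos)
    for (o in oligos) {
        s <- toPseudoSequence(o, map)
        expect_identical(nchar(s), length(o))
        expect_identical(fromPseudoSequence(s, map), encodeOligo(o))
    }
    # shared unit types get the same letter in different oligos
    sa <- strsplit(toPseudoSequence(oligos[[1]], map), "")[[1]]
    sb <- strsplit(toPseudoSequence(oligos[[2]], map), "")[[1]]
    expect_identical(sa[2], sb[1])  # IdoA2S-GlcNS6S in both
    # unmapped disaccharide names its code
    other <- parseHSStructure("IdoA-GlcNH2", id = "z")
    expect_error(toPseudoSequence(other, map), "not in the alphabet map")
    # gaps are dropped on back-translation
    expect_identical(fromPseudoSequence(paste0("-", substr(toPseudoSequence(
        oligos[[1]], map), 1, 2), "-"), map),
        substr(encodeOligo(oligos[[1]]), 1, 22))
})

test_that("pseudoSequences returns a named AAStringSet", {
    oligos <- toy_oligos()
    ss <- pseudoSequences(oligos)
    expect_s4_class(ss, "AAStringSet")
    expect_identical(names(ss), c("a", "b", "c"))
    expect_identical(Biostrings::width(ss),
                     vapply(oligos, length, integer(1)))
})
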