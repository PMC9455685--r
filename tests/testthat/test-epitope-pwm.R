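test_that("the IC50 weighting rule reproduces its worked examples", {
    expect_identical(ic50ToCopies(25), 4L)
    expect_identical(ic50ToCopies(1), 100L)
    expect_identical(ic50ToCopies(50), 2L)
    expect_identical(ic50ToCopies(3), 33L)       # round(100/3)
    expect_identical(ic50ToCopies(200), 1L)      # floor of one copy
    expect_identical(ic50ToCopies(c(25, 1, 50)), c(4L, 100L, 2L))
    expect_error(ic50ToCopies(0), "> 0")
    expect_error(ic50ToCopies(-3), "> 0")
})

test_that("copy counts are antitone in IC50 and scale with the reference", {
    set.seed(5)
    ic <- sort(stats::rlnorm(50, log(20), 1))
    copies <- ic50ToCopies(ic)
    expect_true(all(diff(copies) <= 0L))
    expect_true(all(copies >= 1L))
    # halving the reference halves copies up to rounding (and the floor)
    c50 <- ic50ToCopies(ic, reference = 50)
    expect_true(all(abs(c50 - copies / 2) <= 1))
})

test_that("the weighted MSF carries the copy counts and catches bad panels", {
    oligos <- toy_oligos()[1:2]
    rec <- data.frame(oligo_id = c("a", "b"), ic50 = c(25, 1))
    msf <- buildWeightedMSF(oligos, rec)
    expect_identical(sum(copyCounts(msf)), 104L)  # 4 + 100
    expect_identical(unname(copyCounts(msf)), c(4L, 100L))
    expect_identical(gsub("-", "", alignedSequences(msf)[["a"]]),
                     toPseudoSequence(oligos[[1]], msf@alphabet))
    # single-oligo degenerate panel
    one <- buildWeightedMSF(oligos[1],
                            data.frame(oligo_id = "a", ic50 = 10))
    expect_identical(unname(copyCounts(one)), 10L)
    expect_identical(unname(alignedSequences(one)),
                     toPseudoSequence(oligos[[1]], one@alphabet))
    # missing / duplicate records name the oligo
    expect_error(buildWeightedMSF(oligos,
        data.frame(oligo_id = "a", ic50 = 25)), "b")
    expect_error(buildWeightedMSF(oligos,
        data.frame(oligo_id = c("a", "a", "b"), ic50 = c(1, 2, 3))),
        "duplicate.*a")
})

test_that("computePWM equals the copy-expansion oracle on random instances", {
    set.seed(314)
    for (i in 1:60) {
        msf <- random_msf(nSeq = sample(2:6, 1), L = sample(2:8, 1),
                          nLetters = sample(3:6, 1))
        pwm <- computePWM(msf)
        ora <- pwm_oracle(msf@aligned,
                          rep(1L, length(msf@aligned)) * msf@copies,
                          alphabetLetters(msf@alphabet))
        expect_equal(unname(pwmFrequencies(pwm)), unname(ora$freq),
                     tolerance = 1e-12)
        expect_equal(informationContent(pwm), ora$info, tolerance = 1e-12)
        # copy-weighted gap fraction: oracle expands physically
        exp_gapf <- vapply(seq_len(nchar(msf@aligned[1])), function(j) {
            ch <- substr(rep(msf@aligned, msf@copies), j, j)
            mean(ch == "-")
        }, numeric(1))
        expect_equal(gapFraction(pwm), exp_gapf, tolerance = 1e-12)
        cs <- colSums(pwmFrequencies(pwm))
        expect_true(all(abs(cs - ifelse(pwm@allGap, 0, 1)) < 1e-12))
        K <- nrow(pwmFrequencies(pwm))
        expect_true(all(informationContent(pwm) >= 0 &
                        informationContent(pwm) <= log2(K) + 1e-12))
    }
})

test_that("closed-form PWM columns come out exactly", {
    # single letter at K = 20 -> information log2(20)
    msf <- make_msf(c("A", "A"), c(2, 3), nLetters = 20)
    pwm <- computePWM(msf)
    expect_equal(unname(pwmFrequencies(pwm)["A", 1]), 1)
    expect_equal(informationContent(pwm), log2(20))
    # uniform over 4 letters at K = 4 -> information 0
    msf4 <- make_msf(c("A", "C", "D", "E"), rep(1, 4), nLetters = 4)
    expect_equal(informationContent(computePWM(msf4)), 0)
    # weighted counts: {("AB"-like, 3 copies), ("CB"-like, 1 copy)}
    msfw <- make_msf(c("AC", "CC"), c(3, 1), nLetters = 4)
    f <- pwmFrequencies(computePWM(msfw))
    expect_equal(unname(f[c("A", "C"), 1]), c(0.75, 0.25))
    expect_equal(unname(f["C", 2]), 1)
})

test_that("all-gap columns are flagged with zero information", {
    msf <- make_msf(c("A-C", "A-D"), c(1, 2), nLetters = 4)
    pwm <- computePWM(msf)
    expect_identical(pwm@allGap, c(FALSE, TRUE, FALSE))
    expect_equal(informationContent(pwm)[2], 0)
    expect_equal(gapFraction(pwm)[2], 1)
    expect_equal(colSums(pwmFrequencies(pwm))[2], 0, ignore_attr = TRUE)
})

test_that("the small-sample correction subtracts (K-1)/(2 ln2 n), clamped", {
    msf <- make_msf(c("A", "A"), c(2, 2), nLetters = 4)
    raw <- informationContent(computePWM(msf))
    corr <- informationContent(computePWM(msf, smallSampleCorrection = TRUE))
    expect_equal(corr, raw - 3 / (2 * log(2) * 4))
    # clamp: a zero-information column cannot go negative
    msf0 <- make_msf(c("A", "C"), c(1, 1), nLetters = 2)
    expect_equal(
        informationContent(computePWM(msf0, smallSampleCorrection = TRUE)),
        0)
})

test_that("back-translation to the HS logo preserves every number", {
    set.seed(27)
    msf <- random_msf(4, 6, nLetters = 5, gapProb = 0.15)
    pwm <- computePWM(msf)
    logo <- pwmToHSLogo(pwm)
    map <- msf@alphabet
    expect_identical(rownames(logo@freq),
                     alphabetCodes(map))
    expect_equal(unname(logo@freq), unname(pwmFrequencies(pwm)))
    expect_equal(logo@info, informationContent(pwm))
    # heights per column sum to the column information
    expect_equal(colSums(logo@heights), informationContent(pwm))
    # inverse relabeling recovers the original matrix
    back <- logo@freq
    rownames(back) <- alphabetLetters(map)[match(rownames(logo@freq),
                                                 alphabetCodes(map))]
    expect_equal(back[rownames(pwmFrequencies(pwm)), ],
                 pwmFrequencies(pwm))
    # a letter outside the map is an error
    small <- alphabetFromCodes(alphabetCodes(map)[1:2])
    expect_error(pwmToHSLogo(pwm, small), "not in the alphabet map")
})

test_that("logo tables carry frequency-height pairs per column", {
    msf <- make_msf(c("AC", "CC"), c(3, 1), nLetters = 4)
    lt <- logoTable(pwmToHSLogo(computePWM(msf)))
    expect_identical(colnames(lt),
                     c("position", "code", "frequency", "height"))
    expect_equal(sum(lt$frequency[lt$position == 1]), 1)
})

test_that("oligo match scores have their closed forms and window maximum", {
    msf <- make_msf(c("ACD", "ACD"), c(1, 1), nLetters = 4)
    pwm <- computePWM(msf)  # degenerate frequency-1 PWM, K = 4
    map <- msf@alphabet
    consensus <- decodeOligo(fromPseudoSequence("ACD", map), "cons")
    expect_equal(scoreOligo(pwm, consensus), 3 * log2(4))
    # no letter in the support: floor at L * log2(pseudocount * K)
    off <- decodeOligo(fromPseudoSequence("EEE", map), "off")
    expect_equal(scoreOligo(pwm, off), 3 * log2(1e-3 * 4))
    # sliding: the best window of a longer oligo still hits the maximum
    long <- decodeOligo(fromPseudoSequence("EACDE", map), "long")
    expect_equal(scoreOligo(pwm, long), 3 * log2(4))
    # explicit exhaustive window oracle
    pc <- 1e-3
    lw <- function(seqLetters, startCol) {
        sum(vapply(seq_along(seqLetters), function(k) {
            p <- pwmFrequencies(pwm)[seqLetters[k], startCol + k - 1]
            log2(max(p, pc) * 4)
        }, numeric(1)))
    }
    sl <- strsplit("EACDE", "")[[1]]
    best <- max(vapply(1:3, function(s) lw(sl[s:(s + 2)], 1), numeric(1)))
    expect_equal(scoreOligo(pwm, long), best)
})
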