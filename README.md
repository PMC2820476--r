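# dupdist

Exact algorithms for the **duplication distance** family of genomic
distances.  Large segmental duplications (low-copy repeats) in mammalian
genomes are mosaics of smaller repeated units; a parsimonious model of
their construction copies substrings of a fixed source string `x` and
pastes them into an initially empty target until the observed block `y`
is assembled.  `dupdist` computes the minimum-cost such construction — and
reconstructs one optimal scenario — for five operation sets:

| variant | operations | cost per operation |
|---|---|---|
| `dup` | duplicate | Δ₁ + ℓΔ₂ |
| `dupdel` | duplicate with internal runs deleted | Δ₁ + ℓΔ₂ + ΣΦ(gap) |
| `dupinv` | duplicate, duplicate-invert (signed strings) | Δ₁ + ℓΔ₂ / Θ₁ + ℓΘ₂ |
| `dupinvdel` | both, with internal deletions | as above + ΣΦ(gap) |
| `dupsubinv` | duplicate with one in-place inverted substring | Δ₁ + ℓΔ₂ + Θ(ℓᵢₙᵥ) + ΣΦ(gap) |

All five are memoized interval dynamic programs over the target, built on
the *non-overlapping property*: the characters contributed by distinct
operations form subsequences of `y` that never interleave.  With unit
costs the plain distance also equals the minimum number of nontrivial
productions in a parse of `y` under the context-free grammar
`S → x_i S x_{i+1} S … x_j S | ε`, which the package exposes directly.
A brute-force oracle (exhaustive partition enumeration, plus a bounded
search over unfused duplicate/delete sequences) provides ground truth on
tiny instances, and seeded generators produce synthetic strings and
scenarios with certified cost bounds.

## Worked example

```r
library(dupdist)

dupDistance("abcd", "bbccd")
#> [1] 2

sc <- dupTraceback("abcd", "bbccd")
sc
#> DupScenario: 2 op(s), total cost 2
#> DUP x[2..4] -> pos 1
#> DUP x[2..3] -> pos 2

replayScenario(signedString("abcd"), sc)$target
#> SignedString of length 5: bbccd
```

Two operations are optimal: `bbccd` is not a substring of `abcd`, so one
copy cannot do it; the first operation pastes `bcd`, the second pastes
`bc` inside it.  Signed strings and richer operation sets work the same
way:

```r
dupDistance("+a +b +c", "-c -b -a", variant = "dupinv")
#> [1] 1

dupDistance("abcde", "ace", costModel(3, 1, phi = c(0, 1)), "dupdel")
#> [1] 10
```

The second call prices a single operation that copies `abcde` (cost
3 + 5·1) and deletes the runs `b` and `d` (cost 1 each) before pasting.

The grammar view:

```r
formatRules(dupGrammar("ab"))
#> [1] "S -> a S"     "S -> a S b S" "S -> b S"     "S -> ε"

nontrivialProductions(minProductionParse("abcd", "bbccd"))
#> [1] 2
```

A command-line wrapper is installed at `inst/scripts/dupdist`:

```sh
Rscript inst/scripts/dupdist distance --variant dup --source abcd --target bbccd
# 2
```

## Package layout

* `R/signedString.R`, `R/operations.R` — signed strings, the six
  operation kinds, replay, positional-relation classification
* `R/dp.R`, `R/distances.R` — the shared interval DP engine, the five
  distances, traceback
* `R/oracle.R` — partition-enumeration oracle, bounded unfused search,
  scenario canonicalization
* `R/grammar.R` — grammar emission, minimum-production parsing
* `R/synth.R`, `R/io.R`, `R/cli.R` — generators, scenario JSON, CLI
* `vignettes/duplication-distances.Rmd` — models, recurrences, design
  notes and limitations
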