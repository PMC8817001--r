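# tacitcoord

Analysis of behaviour in **"Assign Circles" tacit coordination games** —
grid boards on which two players, unable to communicate, each connect every
circle to one of two squares and succeed only if their complete assignments
coincide. The package is for behavioural game theorists and cognitive
modelers who want to measure how well individuals coordinate, which
focal-point heuristics they use, and how the two are related — either on
their own experimental data (boards as JSON, responses as CSV) or on fully
synthetic agent populations it generates itself.

## What it computes

**Rule engine.** The three classical selection rules, each applicable on a
board only when it implies a unique full assignment (any distance tie makes
it inapplicable):

* *closeness* — each circle to its strictly nearer square;
* *accession* — each 4-connected group of circles to the square nearer to
  the group (minimum distance over the group's circles);
* *equality* — when a vertical line puts exactly half the circles strictly
  on each side, the left half goes to the left square.

**Coordination statistics.** For a game with solution counts *m<sub>j</sub>*
over *N* players, the coordination index

> *c* = Σ<sub>j</sub> *m<sub>j</sub>*(*m<sub>j</sub>* − 1) / (*N*(*N* − 1))

is the probability two randomly drawn players coincide (1/2<sup>n</sup>
under random picking on an n-circle board). A player's individual
coordination ability iCA(*i*) = Σ<sub>j≠i</sub>Σ<sub>k</sub>
CF(*i*,*j*,*k*) / ((*N*−1)*t*) averages exact-match coordination against
all other players over the *t* predefined games. Game tags code each
(player, game, rule) as +1/0/−1 (followed / unavailable / not followed)
and the strategy rate SR = #{+1}/#{±1} summarizes each player's use of
each rule; the three SRs form the player's strategic profile.

**Ability distribution.** Hartigan's dip test of unimodality (an exact
implementation with bootstrap calibration, in C++), plus an
amplitude-parameterized Gaussian mixture curve fit
Σ *a<sub>i</sub>* exp(−((x−*b<sub>i</sub>*)/*c<sub>i</sub>*)²) to the iCA
histogram, with the number of components chosen from the RSS noise floor
and corroborated by the silhouette index.

**Profile → ability model.** PCA on the standardized SR triple, compression
to the two leading projections (S1, S2), ordinary least squares
iCA = β₀ + β₁S1 + β₂S2, and external validation by per-player relative
absolute error percentiles.

**Synthetic populations.** Seeded agents defined by rule propensities and
a choice-noise level, three ability strata reproducing the multimodal
shape of observed ability scores, ten built-in boards matching the
classical battery's rule-applicability pattern, plus random board
generation under constraints.

## Worked example

```r
library(tacitcoord)

profile_board(predefined_boards()[[10]])
#> <board_rule_profile 'predef_10'>
#>   closeness LLRRR
#>   equality  None
#>   accession LLLRR
#>   predicted: LLRRR or LLLRR
```

Five circles: equality is blocked (no even split), and closeness and
accession disagree about the third circle — it is nearer the right square,
but its connected group is nearer the left one — so the board has two
competing focal points.

```r
res <- run_pipeline(run_config(mode = "synthetic", seed = 42))
res
#> <pipeline_result> 93 players, 14 games (synthetic mode, seed 42)
#>   iCA: dip = 0.0336 (p = 0.476), mixture k = 2 (silhouette k = 2)
#>   model: R^2 = 0.8820; validation median |error| = 5.67% (independent validation population)

head(res$scores, 3)
#>           player       ica sr_closeness sr_equality sr_accession
#> 1 agent_001_high 0.5663043    0.7777778        1.00    0.6363636
#> 2 agent_002_high 0.5456522    0.8888889        0.75    0.7272727
#> 3 agent_003_high 0.5673913    0.7777778        1.00    0.6363636

round(res$validation$percentiles, 3)
#>    p25    p50    p75
#>  2.473  5.673 11.737
```

This simulates a 93-agent study population on 14 boards, scores every
player (iCA over the ten predefined boards, SR per rule over all 14),
characterizes the ability distribution, fits the PCA-compressed linear
model (here R² = 0.88 — the strategic profile explains most of the
variance in ability), and validates its predictions on an independently
simulated second population: half the players are predicted within 5.7%
relative error, three quarters within 11.7%. With `out_dir` set, the run
additionally writes `scores.csv`, `games.csv`, `distribution.json`,
`model.json`, `validation.json` and a run log.

A thin command-line wrapper over the same functions lives at
`inst/cli/tacitcoord.R` (`run`, `simulate`, `rules`, `score` subcommands).

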