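---
title: "Rateless erasure codes for DNA data storage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rateless erasure codes for DNA data storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnafountain)
```

## The problem

DNA stores digital data at extreme density, but synthesis, storage and
sequencing each corrupt or lose strands, and some sequences — long
homopolymers, unbalanced GC content, short tandem repeats — are unstable by
construction. Because a strand with a failed integrity check can simply be
discarded, the channel is well modelled as an *erasure* channel: strands
either arrive intact or not at all.

Fountain (rateless erasure) codes fit this channel unusually well. An
encoder cuts the file into $n$ equal *chunks* and can emit an effectively
unlimited stream of *packets*, each the XOR of a pseudo-randomly selected
subset of chunks; any sufficiently large subset of $(1+\varepsilon)\,n$
intact packets reconstructs the file. The rateless property has a second
use in this setting: among the endless supply of candidate packets one can
*select* those whose DNA representation satisfies the biochemical
constraints, rather than transforming the data to satisfy them.

This package implements that whole workflow: three codes (LT, Online,
Raptor), the binary packet format with integrity checks, the
binary-to-nucleotide conversion, a rule engine scoring DNA sequences, and
the driver routines (seed sweeps, bounded selection, erasure simulation,
decode).

## The codes

**LT.** Each packet seed drives a deterministic generator: the first draw
samples a degree $d$ from a Soliton distribution, subsequent draws select
$d$ distinct chunks uniformly; the payload is their XOR. The Ideal Soliton
distribution $\rho(1)=1/N$, $\rho(k)=1/(k(k-1))$ is optimal in expectation
but fragile; the Robust Soliton variant adds the spike term $\tau$ at a
position $K<N$ controlled by a failure parameter $\delta$ and renormalizes.

**Online.** An outer code first builds $M=\lceil 0.55\,q\,\varepsilon\,F\rceil$
auxiliary blocks for $F$ chunks, XORing every chunk into $q$ distinct aux
blocks; the inner code is an LT code over the union of chunks and aux
blocks. The aux blocks insure rarely-covered chunks against the coupon
collector's problem.

**Raptor.** A fixed-rate precode extends the $k$ chunks with $S$ circulant
(LDPC-style) parities and $H$ dense Gray/Half parities, giving
$L=k+S+H$ intermediate symbols; the inner LT code uses the fixed
seven-value degree table over $[0,2^{20})$ and a modular $(d,a,b)$ index
walk over the smallest prime $L'\ge L$. Operation is non-systematic:
chunks never appear verbatim as packets, which also avoids emitting the
raw (constraint-violating) input bytes as DNA.

All three decoders reduce to one linear-algebra object: a GF(2) system
$Ax=b$ with one bit-row per packet (plus one zero-RHS constraint row per
aux/parity symbol) whose right-hand sides are the payload bytes. The
Gaussian solver eliminates purely by row XOR; "partial pivoting" in GF(2)
degenerates to *any* row with a 1 in the pivot column, and rows are taken
in arrival order for determinism. The belief-propagation decoder peels
degree-1 equations transitively; it can only succeed when Gaussian
elimination would (never the reverse), which the test suite checks as a
property. The pseudo-decoder tracks only index sets — no payload work —
and is what the encoder polls in generate-until-decodable mode.

### Decode success

Solvability of the full system means rank $=$ number of unknowns. For the
precoded codes the file is recovered as soon as every *chunk* unknown is
determined, even if some auxiliary/parity unknowns are not; the solver
reports partially determined unknowns (in a reduced basis, unknown $i$ is
determined exactly when its pivot row is the singleton $e_i$) and the
decoder uses them.

## Determinism

Every random choice derives from a documented 32-bit xorshift generator
(shift triple 13/17/5), so packets are bit-reproducible across platforms
and independent of R's global RNG. Two details are part of the seed
contract:

* seeds are first mixed through the MurmurHash3 32-bit finalizer — raw
  xorshift states for consecutive seeds are strongly correlated (a linear
  map), which in early experiments made whole seed ranges draw the same
  degree and inflated LT decode overhead by an order of magnitude;
* a mixed state of 0 (the xorshift fixed point) is remapped to
  `0x9E3779B9`.

Integer draws use reduction mod $n$; the modulo bias is negligible at the
$n$ used here and keeps the draw sequence trivial to reproduce.

## Packet format

Fields travel big-endian in configurable widths: total chunk count
(default 4 bytes, omittable for out-of-band transmission), seed (default
4, commonly 2) or an explicit degree + chunk-id list, payload, checksum.
The checksum — `nocode`, CRC-8 (poly 0x07, init 0, non-reflected), CRC-32
(IEEE reflected) or Reed–Solomon over GF($2^8$) with polynomial 0x11D and
a configurable parity count — covers *all* preceding serialized bytes, not
just the payload: corruption of the seed or chunk-count fields is fatal to
decoding and must not pass silently. Reed–Solomon repairs up to
$\lfloor \text{nsym}/2\rfloor$ byte errors before the packet is accepted;
every other failure converts the packet into an erasure. For seed-based
layouts the serialized length is a pure function of layout and chunk size,
so all DNA strands of one encoding have equal length; explicit-list
layouts grow with the degree.

Bytes map to bases two bits at a time (default `00→A, 01→C, 10→G, 11→T`,
most-significant pair first; any base permutation is legal), giving 4
bases per byte — the ideal information density. FASTA I/O goes through
Biostrings; record order is preserved exactly and bases are normalized to
uppercase.

## The rule engine

Each rule maps a sequence to an error contribution in $[0,1]$; enabled
contributions are *summed* (matching the accumulated-score model) and
scaled, so a sequence violating several rules can exceed 1. The score is
read as the probability the strand is lost over one storage cycle;
`drop_decision()` erases with probability
$\min(\text{score}\times\text{generations}, 1)$.

The GC rule is the clamped quartic
$f(x) = \tfrac{1}{100}\left(-\tfrac{x^4}{7200} + \tfrac{x^3}{36}
- \tfrac{121x^2}{72} + \tfrac{175x}{6} + 100\right)$,
$\mathrm{err} = \max(\min(f,1),0)$: exactly 0 on $[40,60]$, exactly 1 on
$[0,30]\cup[70,100]$, near-linear ramps between. (The implementation
evaluates the polynomial over the common denominator 720000 so that the
plateau boundaries are exact in floating point.) It is applied to the
whole strand and, via a sliding window, to every window (default 50 nt) —
a strand can average 50% GC and still contain an AT-only stretch.

The remaining defaults are package choices drawn from the ranges reported
in the synthesis/sequencing literature, deliberately erring on the high
side (a close upper bound is safer for preselection than an
underestimate), and all overridable through `rule_config()`:

* homopolymer curve: 0 up to run length 3, then 0.3 / 0.7 / 1.0 at 4 / 5 /
  ≥ 6 — runs above ~4 nt are where slippage and miscalls rise sharply;
* dinucleotide repeats fire from 4 units (0.5 / 0.8 / 1.0 at 4 / 5 / ≥ 6),
  trinucleotide from 3 units — the two micro-satellite classes most prone
  to PCR slippage;
* per-base mutation weight 0.002/nt (0.2% per base per cycle, the order of
  magnitude reported across synthesis + sequencing error studies), giving
  e.g. a 0.24 baseline for a 120 nt strand;
* illegal symbols score 1 outright (the strand cannot be synthesized).

Under these defaults, uniformly random 120 nt sequences score a median
above 0.5 — most random DNA is unusable for storage, which is precisely
the argument for letting a rateless code search for compliant packets. The
`erlich_zielinski` preset reproduces the reference screening rule set
(homopolymers > 3 nt or overall GC outside 45–55% reject a strand,
nothing else is scored). The `scale` knob rescales the accumulated score
where the deliberate overestimation is unwanted.

## Driver-level choices

* **Seed sweeps** enumerate the full seed space (65,536 candidates for a
  2-byte seed), score every candidate, and sort by score with ties broken
  by ascending seed — byte-identical output on repeated runs. Widths above
  3 bytes are refused without an explicit override.
* **Bounded encoding**: `strict` accepts only scores ≤ bound; `weak` draws
  $u\in[0,1)$ per packet and accepts when $u \ge$ score, which still makes
  progress when every candidate violates the strict bound. The seed budget
  defaults to the full seed space; exhausting it is a progress error, not
  a hang.
* **Online for very small files**: $M$ can fall below $q$, making "$q$
  distinct aux blocks per chunk" unsatisfiable; the driver then caps the
  effective quality at $M$ (both sides derive the same cap from shared
  parameters). The module-level `build_aux_blocks()` keeps the strict
  $M \ge q$ precondition.
* The Online inner code's default distribution is unspecified in the
  literature on the framework this follows; here it is a Robust Soliton
  with Luby's spike heuristic $K = N/(c\ln(N/\delta)\sqrt{N})$, $c=0.1$,
  $\delta=0.05$.
* **Chunk coverage** expands aux/parity symbols into their constituent
  chunks (XOR-cancelling duplicates) before counting: a packet XORing a
  parity block effectively carries every chunk inside it. This is what
  makes the precoded codes' minimum coverage far higher than LT's at equal
  packet counts.

## Raptor precode: a documented reading

The precode sizing conditions are used exactly as the source framework
prints them: $f(k)$ the smallest $x$ with $x(x-1)\ge 2k$; $S$ the smallest
prime $\ge \lceil 0.01k+f(k)\rceil$; $H$ the smallest $x$ with
$\binom{x}{\lceil x/2\rceil}\ge f(k)+S$. The prime-count blocks get the
circulant construction (each chunk in exactly 3 of the $S$ blocks) and the
binomial-count blocks the Gray/Half construction over the first $k+S$
symbols, preserving the stated staging. Note that the binomial bound
$f+S$ is much smaller than the $k+S$ used by the RFC 5053 family, so $H$
is smaller here (9 instead of 13 at $k=1000$) and weight-$\lceil H/2\rceil$
Gray codewords beyond the first $\binom{H}{\lceil H/2\rceil}$ necessarily
use bit positions $\ge H$; membership takes bits $0..H-1$ literally.

This has a measurable cost: the acceptance suite measures the mean number
of extra packets beyond $k=1000$ needed for a successful decode at about
3 (20 seeded trials), and the same experiment with the RFC-style $H$
bound still measures above 2 for non-systematic random-seed operation —
the "1–2 extra packets" figure often quoted for this construction appears
to presume the systematic variant. The corresponding acceptance check
asserts ≤ 2 and is expected to fail under this faithful construction;
small-$k$ behaviour scales accordingly (~73% decodability at $k=30$ with
32 packets, ~96% with 35).

## Problem sizes in the test suite

The suite exercises round trips at payloads of 1 B–10 kB across all three
codecs and both 2- and 4-byte seeds, solver equivalence on 500 random
systems ≤ 20×20 against a brute-force oracle, the full 65,536-seed sweep,
and 20 decode-overhead trials at $k=1000$ — sizes chosen so the whole
suite runs in a few minutes on one CPU while still covering every
contract.

## What the synthetic inputs do and do not show

Test payloads are uniformly random bytes (plus small text files), which is
the *hardest* case for the rule engine (random DNA scores high) but the
*easiest* for coverage comparisons (truly random chunks make all packets
look alike compositionally). Real files have structure — long constant
runs in images produce homopolymer-heavy packets under systematic codes,
which is an argument for the non-systematic operation used here — and
real channels mutate strands rather than only deleting them; mutation is
modelled solely through checksum-failure erasure and the generations
multiplier, not through explicit substitution/indel simulation. Passing
tests therefore demonstrate the coding and selection machinery, not a
calibrated end-to-end error model for any particular wet-lab protocol.

## Known limitations

* Pure-R bit packing: fine for $k$ up to a few thousand; inactivation
  decoding and sparse-matrix tricks for much larger $k$ are out of scope.
* No sub-block ("source block") partitioning, no RaptorQ, no systematic
  Raptor indexing.
* The rule engine scores and erases; it does not synthesize mutated reads.
* FASTA parsing reports Biostrings' own errors, without line numbers.
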