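---
title: "Designing informationally complex habitat tiles with habtile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing informationally complex habitat tiles with habtile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habtile)
```

## The model: complexity as information content

`habtile` quantifies the complexity of a static substrate as the amount of
information needed to describe its surface. This is *informational*
complexity: no temporal dynamics, no emergent interactions — just the
uncertainty associated with the configuration of non-living objects (pits
in a moulded tile) at a fixed point in time. The model deliberately treats
each object as independent: attractive or clumped point processes, and any
ecological interaction among object types, are out of scope.

Five variables control the information content of a tile:

1. **Number of object types** `k` — more types, more uncertainty.
2. **Relative abundances** `p` — the more even, the harder to predict
   which type occupies a random spot. Quantified by Shannon entropy
   $H(X) = -\sum_i p_i \log_2 p_i$.
3. **Density** `n` — the total object count.
4. **Size variability** — each dimension (footprint, depth) of each type
   is sampled from a distribution; a discrete lattice with many levels
   carries more information than one with few.
5. **Spatial arrangement** — a rule (an ordered grid) compresses the
   description, so a random arrangement is more complex than an ordered
   one at identical numeric settings.

Two conventions are fixed package-wide and recorded in every report:
entropy uses **base 2** (bits; any other base is a constant factor), and
$0 \log 0 := 0$ (the standard limit), so a type can be zeroed out of `p`
without error.

### Size levels and the continuous exclusion

A discrete-uniform dimension with minimum $a$, maximum $b$ and increment
$\delta$ has $(b-a)/\delta + 1$ levels, and its size entropy is
$\log_2(\text{levels})$ under the uniform sampling the generator uses.
Smaller increments over the same range mean more levels, hence more
complexity. A *continuous* range is representable (and fabricable — the
moulds do not care), but the probability of any particular value is zero,
so it admits no finite level count and makes cross-tile comparisons
meaningless. `size_level_count()` therefore raises an
unsupported-comparison error for continuous ranges rather than silently
returning infinity.

### Combinations and the descriptor count

`combination_count(components, descriptors)` returns
$\text{components}^{\text{descriptors}}$ exactly. In
`complexity_report()` the components are the density `n`; the
*descriptors* default to the number of attributes that actually vary:
every size dimension with more than one level, plus type identity itself
when $k > 1$. Which attributes "count" is genuinely a modelling choice
rather than something the mathematics dictates, so the report exposes
`descriptors` as an override instead of hard-coding a list.

### Comparability

Entropy is only meaningful between tiles generated under the same rules.
Each report carries a canonical `comparable_key` built from the
arrangement rule and the set of distribution kinds in the spec;
`is_comparable()` is the gate. Ordered and random tiles are never
comparable, nor are discrete and continuous (or discrete and fixed)
tiles, nor any manually edited design (see below).

## Realising a design

`generate_tile()` is the single entry point. It seeds a Mersenne–Twister
stream from the spec's seed (restoring the caller's RNG state afterwards)
and consumes it in a fixed order — abundance randomisation if requested,
type apportionment, size sampling per type in spec order, then placement —
so a `(spec, seed)` pair reproduces the identical design byte for byte,
across refactors of everything downstream.

* **Apportionment** (`assign_types`) uses largest-remainder rounding of
  $n p$: floors first, then the largest fractional remainders get the
  leftover objects. The RNG is consulted *only* to break exact remainder
  ties, so typical specs apportion deterministically.
* **Random abundances** (`randomize_abundances`) are drawn uniformly from
  the simplex via normalised exponential spacings (a flat Dirichlet).
* **Random placement** (`place_random`) is random sequential adsorption:
  centres proposed uniformly over the admissible rectangle (the tile
  shrunk by each object's half-footprint) and rejected when any pairwise
  edge-to-edge gap falls below the buffer. Buffer semantics are
  *edge-to-edge*, not centre-to-centre: circles use centre distance minus
  the radii, axis-aligned squares the Chebyshev analogue, and a mixed
  circle–square pair the distance from the circle centre to the square's
  boundary (coordinate clamping) minus the radius — the spec leaves mixed
  pairs open, and this is the exact geometric gap. Each object gets up to
  10,000 proposals (tunable); exhaustion raises an infeasible-density
  error carrying diagnostics (attempts, rejection counts, objects
  achieved) so the caller can tell "object larger than tile" from
  "jammed near the packing limit".
* **Boundary rule**: footprints must lie fully inside the tile. A
  fabricated mould cannot have a pit crossing its wall, so edge-clipped
  objects are not allowed.
* **Ordered placement** (`place_ordered`) consumes no randomness: objects
  fill an even $r \times c$ partition of the tile row-major from the
  lower-left origin, with $r = \lceil\sqrt{n}\rceil$ and
  $c = \lceil n/r \rceil$, centres at cell midpoints. Square counts give
  the familiar regular lattice; other counts leave trailing cells empty.
  The result is re-validated against the same containment and buffer
  constraints and refused if the grid is too tight.

An independent validator (`validate_design`) — a separate, vectorised
all-pairs implementation, deliberately sharing no code with the placement
loop — is the single source of truth for feasibility; every generated
design and every strictly accepted edit must leave it silent.

## Surface area

Pits are vertical-walled recesses: the pit floor replaces the opening, so
the planar area is unchanged and each pit contributes only wall area
($4wd$ for a square of side $w$ and depth $d$, $\pi w d$ for a circle of
diameter $w$). This is what makes the paired-tile exercise possible: if
the complex tile's size and depth lattices are symmetric about the simple
tile's fixed values, the expected wall area per pit is identical
($E[wd] = E[w]E[d]$ by independence), so the two tiles have equal surface
area in expectation and complexity is isolated from area.

## Editing and its consequences

`apply_edit()` applies `move`, `resize` and `delete` commands to a copy of
the design (the input is never mutated). Strict mode (the default)
refuses any edit that violates containment or buffer constraints, naming
the offending objects — fabrication safety by default. Permissive mode
attaches the violations as warnings instead. Either way the design is
marked edited: hand placement (and resized dimensions that may leave the
lattice) break the sampling rules, so an edited design's report gets an
`|edited` suffix on its comparability key and is never comparable, even
to its own pre-edit report.

## Export formats

* **CSV**: one row per object
  (`object_id,type_id,shape,centre_x,centre_y,footprint_size,depth`),
  plain UTF-8, decimal point regardless of locale, numbers printed with
  `%.17g` so a write–read cycle reproduces every double bit for bit.
* **DXF**: minimal R12 ASCII — the most widely parseable dialect. The
  tile boundary is a closed polyline on layer `TILE`; circles become
  `CIRCLE` entities and squares closed polylines on a layer per
  `type_id`. DXF has no standard notion of pit depth, so depth is encoded
  as the entity thickness attribute (group 39) and mirrored in a `999`
  comment per entity. Squares are axis-aligned; rotation is not modelled.
* **SVG**: one shape per object, filled by the type's colour, 1 user unit
  per SVG unit, y axis flipped from the tile's lower-left origin to SVG's
  top-left. All writers are deterministic functions of the design.

Tile specs themselves round-trip through a small YAML schema
(`read_spec()` / `write_spec()`); the object-count key is named `density`
because bare `n` is a YAML 1.1 boolean literal.

## Packaged study designs and test conditions

The packaged `simple_tile.yaml` / `complex_tile.yaml` pair emulates the
seawall experiment's tiles: 400×400 mm (60 mm thick), square pits at the
8–56 mm scale. The simple tile fixes footprint 32 mm and depth 24 mm on
an ordered grid; the complex tile uses those values as the means of
discrete lattices (footprint 8–56 by 8; depth 8–40 by 8) with random
placement and an 8 mm buffer. The pit count is not something the tile
dimensions dictate; the package uses 25 (a 5×5 grid), a density at which
random placement of the largest lattice sizes always succeeds — at
substantially higher densities the 56 mm draws approach the jamming
regime of sequential adsorption and placement can legitimately fail. The
depth lattice is the package's choice, kept symmetric about 24 mm so the
equal-area property holds in expectation.

The test suite checks entropy bounds over 1,000 random abundance vectors,
validator silence over 500 generated designs (a mixed family of 1–3
types, both shapes, both arrangements, buffers 0–5 on 150 mm tiles),
lattice membership of 10,000 draws, byte-level determinism, the
infeasibility contract, surface-area parity of the packaged pair over 200
seeds (the mean difference is ~0.2% of the simple tile's area; the
theoretical standard deviation of that 200-seed mean is ~0.33%), and
CSV/DXF parse-back equality over 50 designs. These sizes keep the full
suite under half a minute.

What passing these tests shows — and what it does not: the generator
provably satisfies its own geometric and statistical contracts, but the
synthetic designs are idealised. Real fabricated tiles have casting
tolerances, draft angles and surface texture that the vertical-wall area
model ignores; the entropy of the *inputs* says nothing about which
assemblages will colonise a tile; and no single number can encapsulate
complexity — a report's entropy must travel with the type count, density
and arrangement it was computed under.

## Known limitations

* No clumped or attractive placement, by design.
* Sequential adsorption cannot reach densities a global optimiser could;
  near the jamming limit generation is stochastic in whether it succeeds,
  which is surfaced as the infeasible-density error rather than hidden by
  retrying.
* Only vertical-walled circular and axis-aligned square pits; no
  protrusions, rotations or 3-D meshes (DXF consumers extrude from the
  thickness attribute).
* Entropy comparisons across differently ruled tiles are refused, not
  approximated.
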