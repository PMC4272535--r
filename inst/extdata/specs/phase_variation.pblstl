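# Phase-variation case study: sector-like patterns (regions) in a growing
# bacterial colony. Statements follow the case study's natural-language
# specification, with numeric constants on the scale of the packaged
# 101 x 101 colony generator (40 timepoints, mutant-fraction grids).

# 1. Developed sectors do not disappear during colony growth.
P >= 0.95 [ G [15, 39] (count(regions) > 0) ]

# 2. Sectors dominated by holes (minimum clusteredness below 0.5) are rare.
P < 0.05 [ F [0, 39] ((count(regions) > 0) ^ (min(regions, clusteredness) < 0.5)) ]

# 3. The mean sector density (mutant fraction relative to wild-type)
#    exceeds 0.5 whenever sectors are present.
P > 0.95 [ G [0, 39] ((count(regions) > 0) => (mean(regions, density) > 0.5)) ]

# 4. The mean sector area oscillates at least once (increases, then
#    eventually decreases).
P > 0.5 [ F [0, 19] ((d(mean(regions, area)) > 0) ^ F [0, 18] (d(mean(regions, area)) < 0)) ]

# 5. The mean sector perimeter oscillates repeatedly (nested temporal
#    operators; also serves as a parser/evaluator stress test).
P > 0.6 [ F [0, 9] ((d(mean(regions, perimeter)) > 0) ^ F [0, 9] ((d(mean(regions, perimeter)) < 0) ^ F [0, 9] ((d(mean(regions, perimeter)) > 0) ^ F [0, 9] (d(mean(regions, perimeter)) < 0)))) ]

# 6. Sectors subtending more than 120 degrees at the origin are rare.
#    (The synthetic generator grows much wider sectors than real phase
#    variation colonies, so this statement is expected to be judged FALSE
#    on packaged data; it is kept as a discriminating negative example.)
P < 0.1 [ F [0, 39] (max(regions, angle) > 120) ]

# 7. Sectors develop from the origin outwards: the minimum distance from
#    the origin stays small whenever sectors are present.
P >= 0.95 [ G [5, 39] ((count(regions) > 0) => (min(regions, distanceFromOrigin) < 15)) ]

# 8. Developed sectors maintain a triangular-like shape.
P > 0.8 [ G [20, 39] ((count(regions) > 0) => (max(regions, triangularMeasure) >= 0.5)) ]
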