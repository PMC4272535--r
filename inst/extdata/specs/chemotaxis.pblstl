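# Chemotaxis case study: clusters of cells aggregating toward a 2-D
# Gaussian attractant centred on a 100 x 100 lattice. The space origin
# (49.5, 49.5) coincides with the gradient centre, so proximity to the
# gradient peak is expressed through the distanceFromOrigin measure.
# Traces span simulation steps 0..200 recorded every 5 steps.

# 9. Cells aggregate at the gradient centre: eventually a cluster forms
#    within distance 5 of the origin and persists for 100 steps.
P >= 0.9 [ F [0, 100] (G [0, 100] (count(filter(clusters, distanceFromOrigin < 5)) > 0)) ]

# 10. The mean clusteredness of individual clusters increases at least
#     five times during the simulation.
P > 0.8 [ F [0, 35] ((d(mean(clusters, clusteredness)) > 0) ^ F [0, 35] ((d(mean(clusters, clusteredness)) > 0) ^ F [0, 35] ((d(mean(clusters, clusteredness)) > 0) ^ F [0, 35] ((d(mean(clusters, clusteredness)) > 0) ^ F [0, 35] (d(mean(clusters, clusteredness)) > 0))))) ]

# 11. The Silhouette cluster-validity index (recorded as the
#     avgClusterednessClusters state variable) rarely collapses below 0.2
#     during the first 50 steps.
P < 0.05 [ F [0, 50] ({avgClusterednessClusters} < 0.2) ]

# 12. The number of clusters decreases and remains below 5.
P > 0.75 [ F [0, 100] (G [0, 95] (count(clusters) < 5)) ]

# 13. At least one aggregated cluster is eventually circular.
P >= 0.6 [ F [0, 200] ((count(clusters) > 0) ^ (max(clusters, circularMeasure) >= 0.5)) ]

# 14. The mean cluster density oscillates (cells pile up and disperse):
#     it is rare for the density never to oscillate.
P < 0.1 [ ~ (F [0, 90] ((d(mean(clusters, density)) > 0) ^ F [0, 95] (d(mean(clusters, density)) < 0))) ]
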