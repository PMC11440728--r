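[{"name":"morph_mean_curvature_mean","block":"morphology"},{"name":"morph_mean_curvature_sd","block":"morphology"},{"name":"morph_mean_curvature_skewness","block":"morphology"},{"name":"morph_mean_curvature_kurtosis","block":"morphology"},{"name":"morph_mean_curvature_median","block":"morphology"},{"name":"morph_max_curvature_mean","block":"morphology"},{"name":"morph_max_curvature_sd","block":"morphology"},{"name":"morph_max_curvature_skewness","block":"morphology"},{"name":"morph_max_curvature_kurtosis","block":"morphology"},{"name":"morph_max_curvature_median","block":"morphology"},{"name":"morph_mean_torsion_mean","block":"morphology"},{"name":"morph_mean_torsion_sd","block":"morphology"},{"name":"morph_mean_torsion_skewness","block":"morphology"},{"name":"morph_mean_torsion_kurtosis","block":"morphology"},{"name":"morph_mean_torsion_median","block":"morphology"},{"name":"morph_max_torsion_mean","block":"morphology"},{"name":"morph_max_torsion_sd","block":"morphology"},{"name":"morph_max_torsion_skewness","block":"morphology"},{"name":"morph_max_torsion_kurtosis","block":"morphology"},{"name":"morph_max_torsion_median","block":"morphology"},{"name":"morph_length_mean","block":"morphology"},{"name":"morph_length_sd","block":"morphology"},{"name":"morph_length_skewness","block":"morphology"},{"name":"morph_length_kurtosis","block":"morphology"},{"name":"morph_length_median","block":"morphology"},{"name":"morph_mean_radius_mean","block":"morphology"},{"name":"morph_mean_radius_sd","block":"morphology"},{"name":"morph_mean_radius_skewness","block":"morphology"},{"name":"morph_mean_radius_kurtosis","block":"morphology"},{"name":"morph_mean_radius_median","block":"morphology"},{"name":"morph_straightness_mean","block":"morphology"},{"name":"morph_straightness_sd","block":"morphology"},{"name":"morph_straightness_skewness","block":"morphology"},{"name":"morph_straightness_kurtosis","block":"morphology"},{"name":"morph_straightness_median","block":"morphology"},{"name":"morph_curvature_skewness_mean","block":"morphology"},{"name":"morph_curvature_skewness_sd","block":"morphology"},{"name":"morph_curvature_skewness_skewness","block":"morphology"},{"name":"morph_curvature_skewness_kurtosis","block":"morphology"},{"name":"morph_curvature_skewness_median","block":"morphology"},{"name":"morph_torsion_skewness_mean","block":"morphology"},{"name":"morph_torsion_skewness_sd","block":"morphology"},{"name":"morph_torsion_skewness_skewness","block":"morphology"},{"name":"morph_torsion_skewness_kurtosis","block":"morphology"},{"name":"morph_torsion_skewness_median","block":"morphology"},{"name":"morph_inflection_count_mean","block":"morphology"},{"name":"morph_inflection_count_sd","block":"morphology"},{"name":"morph_inflection_count_skewness","block":"morphology"},{"name":"morph_inflection_count_kurtosis","block":"morphology"},{"name":"morph_inflection_count_median","block":"morphology"},{"name":"morph_total_curvature_mean","block":"morphology"},{"name":"morph_total_curvature_sd","block":"morphology"},{"name":"morph_total_curvature_skewness","block":"morphology"},{"name":"morph_total_curvature_kurtosis","block":"morphology"},{"name":"morph_total_curvature_median","block":"morphology"},{"name":"morph_total_torsion_mean","block":"morphology"},{"name":"morph_total_torsion_sd","block":"morphology"},{"name":"morph_total_torsion_skewness","block":"morphology"},{"name":"morph_total_torsion_kurtosis","block":"morphology"},{"name":"morph_total_torsion_median","block":"morphology"},{"name":"morph_total_vessel_volume_mm3","block":"morphology"},{"name":"org_branch_count","block":"organization"},{"name":"org_junction_count","block":"organization"},{"name":"org_branch_density_cm3","block":"organization"},{"name":"org_junction_density_cm3","block":"organization"},{"name":"org_tip_count","block":"organization"},{"name":"org_nearest_branch_distance_mean","block":"organization"},{"name":"org_nearest_branch_distance_sd","block":"organization"},{"name":"org_nearest_branch_distance_skewness","block":"organization"},{"name":"org_nearest_branch_distance_kurtosis","block":"organization"},{"name":"org_nearest_branch_distance_median","block":"organization"},{"name":"org_orientation_angle_mean","block":"organization"},{"name":"org_orientation_angle_sd","block":"organization"},{"name":"org_orientation_angle_skewness","block":"organization"},{"name":"org_orientation_angle_kurtosis","block":"organization"},{"name":"org_orientation_angle_median","block":"organization"},{"name":"org_orientation_dispersion_mean","block":"organization"},{"name":"org_orientation_dispersion_sd","block":"organization"},{"name":"org_orientation_dispersion_skewness","block":"organization"},{"name":"org_orientation_dispersion_kurtosis","block":"organization"},{"name":"org_orientation_dispersion_median","block":"organization"},{"name":"org_tumor_surface_distance_mean","block":"organization"},{"name":"org_tumor_surface_distance_sd","block":"organization"},{"name":"org_tumor_surface_distance_skewness","block":"organization"},{"name":"org_tumor_surface_distance_kurtosis","block":"organization"},{"name":"org_tumor_surface_distance_median","block":"organization"},{"name":"org_local_spacing_mean","block":"organization"},{"name":"org_local_spacing_sd","block":"organization"},{"name":"org_local_spacing_skewness","block":"organization"},{"name":"org_local_spacing_kurtosis","block":"organization"},{"name":"org_local_spacing_median","block":"organization"}]
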