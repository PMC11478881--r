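identifiers:
  participant_id: unique participant identifier, never missing
demographics:
  ca: chronological age, years (>= 35)
  sex: male / female
  center: recruitment center, categorical
childhood_ses:
  housing_tenure_childhood: rented / one_dwelling / multi_dwelling
  hot_water: 'logical: access to hot water at age 8'
  rooms_childhood: rooms in the childhood home
  persons_childhood: household size in childhood (>= 1)
education:
  education_level: primary / lower_secondary / upper_secondary / post_secondary
adult_ses:
  housing_tenure_adult: rented / one_dwelling / multi_dwelling
  occupational_class: professional_managerial / skilled_non_manual / skilled_manual
    / partly_unskilled_unclassified
  rooms_adult: rooms in the adult home
  persons_adult: adult household size (>= 1)
lifestyle:
  smoking: never / current / former
  drinker_history: lifetime_abstainer / former_drinker / current
  alcohol_responded: 'logical: answered the alcohol questions'
  alcohol_g_day: ethanol intake, g/day (NA for non-responders)
  physical_activity: leisure-time activity, MET-h/day
  bmi: body mass index, kg/m2
mediator_scores:
  lis: lifestyle inflammation score
  dis: dietary inflammation score (weighted food-group sum)
  mds: Mediterranean diet score, integer 0-9
  drinking5: lifetime_abstainer / former_drinker / moderate / heavy / non_responder
  sf36_physical: SF-36 physical component (generator latent)
  sf36_mental: SF-36 mental component (generator latent)
diet_components:
  intake_leafy_greens: standardized food-group component
  intake_other_vegetables: standardized food-group component
  intake_fruit: standardized food-group component
  intake_legumes: standardized food-group component
  intake_whole_grains: standardized food-group component
  intake_refined_grains: standardized food-group component
  intake_red_meat: standardized food-group component
  intake_processed_meat: standardized food-group component
  intake_poultry: standardized food-group component
  intake_fish: standardized food-group component
  intake_low_fat_dairy: standardized food-group component
  intake_high_fat_dairy: standardized food-group component
  intake_nuts_seeds: standardized food-group component
  intake_olive_oil: standardized food-group component
  intake_other_fats: standardized food-group component
  intake_sweets: standardized food-group component
  intake_sugar_beverages: standardized food-group component
  intake_coffee_tea: standardized food-group component
  intake_supplements: standardized food-group component
mds_components:
  mds_vegetables: 'logical: favorable Mediterranean-diet component'
  mds_legumes: 'logical: favorable Mediterranean-diet component'
  mds_fruit_nuts: 'logical: favorable Mediterranean-diet component'
  mds_cereals: 'logical: favorable Mediterranean-diet component'
  mds_fish: 'logical: favorable Mediterranean-diet component'
  mds_meat: 'logical: favorable Mediterranean-diet component'
  mds_dairy: 'logical: favorable Mediterranean-diet component'
  mds_alcohol_moderate: 'logical: favorable Mediterranean-diet component'
  mds_fat_ratio: 'logical: favorable Mediterranean-diet component'
sf36_domains:
  sf36_physical_functioning: SF-36 domain score, 0-100 (higher = better health)
  sf36_role_physical: SF-36 domain score, 0-100 (higher = better health)
  sf36_bodily_pain: SF-36 domain score, 0-100 (higher = better health)
  sf36_general_health: SF-36 domain score, 0-100 (higher = better health)
  sf36_vitality: SF-36 domain score, 0-100 (higher = better health)
  sf36_social_functioning: SF-36 domain score, 0-100 (higher = better health)
  sf36_role_emotional: SF-36 domain score, 0-100 (higher = better health)
  sf36_mental_health: SF-36 domain score, 0-100 (higher = better health)
inflammatory_biomarkers:
  hscrp: synthetic high-sensitivity C-reactive protein analog (z-scale)
  il6: synthetic interleukin-6 analog
  il8: synthetic interleukin-8 analog
  il10: synthetic interleukin-10 analog
disease_flags:
  cvd: 'logical: prevalent condition'
  cancer: 'logical: prevalent condition'
  diabetes: 'logical: prevalent condition'
  hypertension: 'logical: prevalent condition'
  hyperlipidemia: 'logical: prevalent condition'
markers:
  glucose: circulating blood marker
  insulin: circulating blood marker
  hdl_cholesterol: circulating blood marker
  ldl_cholesterol: circulating blood marker
  triglycerides: circulating blood marker
  creatinine: circulating blood marker
  urea: circulating blood marker
  uric_acid: circulating blood marker
  alt: circulating blood marker
  ast: circulating blood marker
  ggt: circulating blood marker
  alkaline_phosphatase: circulating blood marker
  total_bilirubin: circulating blood marker
  albumin: circulating blood marker
  total_protein: circulating blood marker
  c_reactive_protein: circulating blood marker
  fibrinogen: circulating blood marker
  wbc: circulating blood marker
  rbc: circulating blood marker
  hemoglobin: circulating blood marker
  mcv: circulating blood marker
  mchc: circulating blood marker
  rdw: circulating blood marker
  platelets: circulating blood marker
  mpv: circulating blood marker
  lymphocytes: circulating blood marker
  neutrophils: circulating blood marker
  monocytes: circulating blood marker
  eosinophils: circulating blood marker
  basophils: circulating blood marker
  sodium: circulating blood marker
  potassium: circulating blood marker
  calcium: circulating blood marker
  iron: circulating blood marker
  ferritin: circulating blood marker
  tsh: circulating blood marker
  cholesterol: circulating blood marker
  plateletcrit: circulating blood marker
  hematocrit: circulating blood marker
  mean_corpuscular_hemoglobin: circulating blood marker
outcomes:
  delta_age: delta age = biological - chronological age, years
  ba: biological age from the clock, years (after fit_clock)
  split: train / test clock split (after fit_clock)
  trajectory: 8-level SES trajectory (after score_ses)
  trajectory_true: generator's sampled trajectory (synthetic cohorts only)
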