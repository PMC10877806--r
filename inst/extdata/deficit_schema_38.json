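{
  "version": "replica-38-v1",
  "comment": "Replica deficit schema: 38 deficits across the six published categories. The exact deficit list and grading maps of the source cohort are not public; gradings here are explicit, documented assumptions and can be substituted by editing this file.",
  "deficits": [
    {"name": "cardiovascular_disease", "category": "Self-reported disease or condition", "source_variable": "cardiovascular_disease", "coding": {"no": 0, "yes": 1}},
    {"name": "cancer", "category": "Self-reported disease or condition", "source_variable": "cancer", "coding": {"no": 0, "yes": 1}},
    {"name": "diabetes", "category": "Self-reported disease or condition", "source_variable": "diabetes", "coding": {"no": 0, "yes": 1}},
    {"name": "chronic_lung_disease", "category": "Self-reported disease or condition", "source_variable": "chronic_lung_disease", "coding": {"no": 0, "yes": 1}},
    {"name": "osteoporosis", "category": "Self-reported disease or condition", "source_variable": "osteoporosis", "coding": {"no": 0, "yes": 1}},
    {"name": "arthritis", "category": "Self-reported disease or condition", "source_variable": "arthritis", "coding": {"no": 0, "yes": 1}},
    {"name": "hypertension", "category": "Self-reported disease or condition", "source_variable": "hypertension", "coding": {"no": 0, "yes": 1}},
    {"name": "kidney_disease", "category": "Self-reported disease or condition", "source_variable": "kidney_disease", "coding": {"no": 0, "yes": 1}},
    {"name": "thyroid_disease", "category": "Self-reported disease or condition", "source_variable": "thyroid_disease", "coding": {"no": 0, "yes": 1}},
    {"name": "stroke", "category": "Self-reported disease or condition", "source_variable": "stroke", "coding": {"no": 0, "yes": 1}},
    {"name": "help_shopping", "category": "General daily function", "source_variable": "help_shopping", "coding": {"no help": 0, "some help": 0.5, "dependent": 1}},
    {"name": "help_housework", "category": "General daily function", "source_variable": "help_housework", "coding": {"no help": 0, "some help": 0.5, "dependent": 1}},
    {"name": "help_meal_preparation", "category": "General daily function", "source_variable": "help_meal_preparation", "coding": {"no help": 0, "some help": 0.5, "dependent": 1}},
    {"name": "help_managing_medication", "category": "General daily function", "source_variable": "help_managing_medication", "coding": {"no": 0, "yes": 1}},
    {"name": "help_managing_finances", "category": "General daily function", "source_variable": "help_managing_finances", "coding": {"no": 0, "yes": 1}},
    {"name": "difficulty_lift_carry", "category": "General daily function", "source_variable": "difficulty_lift_carry", "coding": {"not limited": 0, "limited a little": 0.5, "limited a lot": 1}},
    {"name": "uses_walking_aid", "category": "General daily function", "source_variable": "uses_walking_aid", "coding": {"no": 0, "yes": 1}},
    {"name": "help_personal_care", "category": "General daily function", "source_variable": "help_personal_care", "coding": {"no": 0, "yes": 1}},
    {"name": "limitation_moderate_activities", "category": "Physical function and activity level", "source_variable": "limitation_moderate_activities", "coding": {"not limited": 0, "limited a little": 0.5, "limited a lot": 1}},
    {"name": "limitation_climbing_stairs", "category": "Physical function and activity level", "source_variable": "limitation_climbing_stairs", "coding": {"not limited": 0, "limited a little": 0.5, "limited a lot": 1}},
    {"name": "limitation_walking_500m", "category": "Physical function and activity level", "source_variable": "limitation_walking_500m", "coding": {"not limited": 0, "limited a little": 0.5, "limited a lot": 1}},
    {"name": "low_grip_strength", "category": "Physical function and activity level", "source_variable": "low_grip_strength", "coding": {"no": 0, "yes": 1}},
    {"name": "slow_gait_speed", "category": "Physical function and activity level", "source_variable": "slow_gait_speed", "coding": {"no": 0, "yes": 1}},
    {"name": "low_physical_activity", "category": "Physical function and activity level", "source_variable": "low_physical_activity", "coding": {"active": 0, "moderately active": 0.5, "inactive": 1}},
    {"name": "balance_problems", "category": "Physical function and activity level", "source_variable": "balance_problems", "coding": {"no": 0, "yes": 1}},
    {"name": "fall_last_year", "category": "Physical function and activity level", "source_variable": "fall_last_year", "coding": {"no": 0, "yes": 1}},
    {"name": "poor_self_rated_health", "category": "Self-reported health", "source_variable": "self_rated_health", "coding": {"excellent": 0, "very good": 0.25, "good": 0.5, "fair": 0.75, "poor": 1}},
    {"name": "health_worse_than_peers", "category": "Self-reported health", "source_variable": "health_vs_peers", "coding": {"better": 0, "same": 0.5, "worse": 1}},
    {"name": "fatigue", "category": "Self-reported health", "source_variable": "fatigue", "coding": {"none": 0, "mild": 0.5, "severe": 1}},
    {"name": "chronic_pain", "category": "Self-reported health", "source_variable": "chronic_pain", "coding": {"none": 0, "mild": 0.5, "severe": 1}},
    {"name": "sleep_problems", "category": "Self-reported health", "source_variable": "sleep_problems", "coding": {"no": 0, "yes": 1}},
    {"name": "feels_depressed", "category": "Mood/State of mind", "source_variable": "feels_depressed", "coding": {"none": 0, "some of the time": 0.5, "most of the time": 1}},
    {"name": "feels_nervous", "category": "Mood/State of mind", "source_variable": "feels_nervous", "coding": {"none": 0, "some of the time": 0.5, "most of the time": 1}},
    {"name": "low_energy", "category": "Mood/State of mind", "source_variable": "low_energy", "coding": {"none": 0, "some of the time": 0.5, "most of the time": 1}},
    {"name": "loneliness", "category": "Mood/State of mind", "source_variable": "loneliness", "coding": {"none": 0, "some of the time": 0.5, "most of the time": 1}},
    {"name": "lack_of_calm", "category": "Mood/State of mind", "source_variable": "lack_of_calm", "coding": {"none": 0, "some of the time": 0.5, "most of the time": 1}},
    {"name": "lost_interest", "category": "Mood/State of mind", "source_variable": "lost_interest", "coding": {"no": 0, "yes": 1}},
    {"name": "mmse_impairment", "category": "Cognitive function (MMSE)", "source_variable": "mmse_band", "coding": {"28-30": 0, "24-27": 0.5, "<24": 1}}
  ]
}
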