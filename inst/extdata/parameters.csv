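name,base,low,high,units,note
stroke_h0,0.008,0.005,0.012,per year,baseline first-stroke hazard at reference (age 65 male; risk factors at reference)
stroke_age_slope,0.065,0.05,0.08,per year of age,log-linear age effect on stroke hazard
stroke_female_hr,0.85,0.75,0.95,ratio,female vs male stroke hazard
stroke_afib_hr,2.5,2.0,3.5,ratio,atrial fibrillation effect on stroke hazard
stroke_mi_history_hr,1.3,1.1,1.6,ratio,prior MI effect on stroke hazard
stroke_recurrence_mult,2.5,1.8,3.5,ratio,post-stroke recurrent-stroke hazard multiplier
stroke_case_fatality,0.18,0.12,0.25,probability,death in the year of an acute stroke
mi_h0,0.012,0.008,0.018,per year,baseline MI hazard at reference
mi_age_slope,0.05,0.04,0.07,per year of age,log-linear age effect on MI hazard
mi_female_hr,0.7,0.6,0.85,ratio,female vs male MI hazard
mi_history_mult,2.0,1.5,3.0,ratio,recurrent-MI hazard multiplier
mi_case_fatality,0.15,0.10,0.22,probability,death in the year of an acute MI
mort_h0,0.012,0.009,0.016,per year,other-cause death hazard at age 65 (general population)
mort_age_slope,0.09,0.08,0.10,per year of age,Gompertz slope of other-cause mortality
mort_dm_mult,1.5,1.3,1.8,ratio,type 2 diabetes multiplier on other-cause mortality
mort_post_stroke_mult,2.0,1.5,3.0,ratio,post-stroke multiplier on other-cause mortality
hr_hba1c,0.88,0.80,0.95,per 1% decrease,stroke hazard ratio per 1% HbA1c decrease
hr_sbp,0.75,0.65,0.85,per 10 mmHg decrease,stroke hazard ratio per 10 mmHg SBP decrease
hr_lipid,0.90,0.84,0.96,per 1 unit decrease,stroke hazard ratio per 1 unit lipid-ratio decrease
hr_bmi,0.99,0.97,1.00,per 1 kg/m2 decrease,stroke hazard ratio per 1 kg/m2 BMI decrease
mi_hr_hba1c,0.85,0.78,0.93,per 1% decrease,MI hazard ratio per 1% HbA1c decrease
mi_hr_sbp,0.80,0.70,0.90,per 10 mmHg decrease,MI hazard ratio per 10 mmHg SBP decrease
mi_hr_lipid,0.75,0.65,0.85,per 1 unit decrease,MI hazard ratio per 1 unit lipid-ratio decrease
mi_hr_bmi,0.985,0.96,1.00,per 1 kg/m2 decrease,MI hazard ratio per 1 kg/m2 BMI decrease
ref_hba1c,7,7,7,%,reference HbA1c for hazard-ratio anchoring
ref_sbp,140,140,140,mmHg,reference SBP for hazard-ratio anchoring
ref_lipid,4,4,4,unitless,reference total-cholesterol/HDL ratio
ref_bmi,30,30,30,kg/m2,reference BMI
rrr_aspirin,0.12,0.05,0.20,fraction,relative stroke risk reduction on aspirin
rrr_aspirin_mi,0.10,0.02,0.18,fraction,relative MI risk reduction on aspirin
rrr_noac,0.64,0.50,0.74,fraction,relative stroke risk reduction on NOAC (AFib)
rrr_statin_direct,0.15,0.08,0.25,fraction,direct relative stroke risk reduction on statin (beyond lipid lowering)
rrr_statin_mi,0.30,0.20,0.40,fraction,relative MI risk reduction on statin (beyond lipid lowering)
eff_hba1c_per_rung,0.7,0.4,1.0,% HbA1c,HbA1c reduction per glycemic-ladder escalation
eff_sbp_per_rung,5,3,8,mmHg,SBP reduction per BP-ladder escalation
eff_dbp_per_rung,3,2,5,mmHg,DBP reduction per BP-ladder escalation
eff_lipid_statin_moderate,0.8,0.5,1.1,lipid-ratio units,lipid-ratio reduction on moderate-intensity statin
eff_lipid_statin_high,1.2,0.9,1.6,lipid-ratio units,lipid-ratio reduction on high-intensity statin
drift_hba1c,0.08,0.04,0.12,% per year,annual HbA1c drift (natural history)
drift_sbp,0.8,0.4,1.2,mmHg per year,annual SBP drift
drift_lipid,0.01,0.00,0.03,units per year,annual lipid-ratio drift
drift_bmi,0.05,0.00,0.10,kg/m2 per year,annual BMI drift
hypo_rate_basal,0.3,0.1,0.6,episodes per year,severe hypoglycemia rate on basal insulin
hypo_rate_intensive,1.2,0.6,2.0,episodes per year,severe hypoglycemia rate on intensive insulin
cost_glycemic_rung0,50,25,100,USD per year,lifestyle intervention
cost_glycemic_rung1,250,150,400,USD per year,one oral agent
cost_glycemic_rung2,500,300,800,USD per year,two oral agents
cost_glycemic_rung3,4000,3000,5500,USD per year,basal insulin
cost_glycemic_rung4,9000,7000,12000,USD per year,intensive insulin therapy
cost_glycemic_rung3_reduced,1500,1000,2000,USD per year,basal insulin at reduced list prices
cost_glycemic_rung4_reduced,3500,2500,4500,USD per year,intensive insulin at reduced list prices
cost_bp_per_rung,100,60,160,USD per year per rung,antihypertensive medication per half-dose step
cost_statin_moderate,150,90,250,USD per year,moderate-intensity statin
cost_statin_high,300,180,480,USD per year,high-intensity statin
cost_aspirin,20,10,40,USD per year,low-dose aspirin
cost_warfarin,600,400,900,USD per year,warfarin including INR monitoring
cost_noac,5500,4000,7000,USD per year,NOAC
cost_stroke_acute,25000,18000,35000,USD,acute stroke event (hospitalisation and rehabilitation)
cost_stroke_annual,12000,8000,17000,USD per year,chronic post-stroke care
cost_mi_acute,22000,16000,30000,USD,acute MI event
cost_mi_annual,3500,2500,5000,USD per year,chronic post-MI care
cost_death,10000,6000,15000,USD,end-of-life care
cost_smoking_program,500,300,800,USD one-time,behavioural smoking-cessation intervention
cost_weight_program,800,500,1200,USD one-time,structured weight-loss programme
util_baseline,0.80,0.75,0.85,utility,baseline utility with T2D and no stroke
du_stroke_acute,0.25,0.18,0.32,utility decrement,acute stroke year
du_post_stroke,0.15,0.10,0.20,utility decrement,post-stroke state (annual)
du_post_mi,0.05,0.03,0.08,utility decrement,post-MI state (annual)
du_insulin_basal,0.02,0.01,0.04,utility decrement,basal insulin injections and monitoring
du_insulin_intensive,0.04,0.02,0.06,utility decrement,intensive insulin injections and monitoring
du_hypo_episode,0.004,0.002,0.008,utility decrement,per severe hypoglycemia episode
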