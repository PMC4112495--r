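feature,timepoint,published_n,published_den,cohort_n,cohort_den
limb_rigidity,presentation,65,114,10,17
limb_rigidity,ever,153,180,13,18
bradykinesia_clumsy_limb,presentation,53,111,10,17
bradykinesia_clumsy_limb,ever,126,165,11,18
bradykinesia,presentation,NA,NA,8,16
bradykinesia,ever,NA,NA,11,17
clumsy_limb,presentation,NA,NA,10,17
clumsy_limb,ever,NA,NA,10,18
postural_instability,presentation,20,49,4,16
postural_instability,ever,73,94,8,17
falls,presentation,27,76,3,14
falls,ever,83,111,8,15
abnormal_gait,presentation,30,92,5,17
abnormal_gait,ever,102,140,13,18
axial_rigidity,presentation,18,67,4,15
axial_rigidity,ever,68,98,5,16
tremor,presentation,17,83,7,15
tremor,ever,50,127,8,16
limb_dystonia,presentation,18,91,4,17
limb_dystonia,ever,47,123,6,18
myoclonus,presentation,14,94,2,15
myoclonus,ever,34,128,5,15
cognitive_impairment,presentation,59,114,14,18
cognitive_impairment,ever,123,175,17,19
behavioural_changes,presentation,52,113,9,17
behavioural_changes,ever,82,150,14,18
limb_apraxia,presentation,46,102,11,17
limb_apraxia,ever,81,142,14,18
aphasia,presentation,40,101,10,19
aphasia,ever,80,155,11,20
depression,presentation,21,80,3,16
depression,ever,42,82,4,17
cortical_sensory_loss,presentation,20,81,4,17
cortical_sensory_loss,ever,29,107,5,18
alien_limb,presentation,20,90,5,17
alien_limb,ever,24,81,5,18
abnormal_eye_movement,presentation,29,88,7,16
abnormal_eye_movement,ever,90,150,8,16
hyperreflexia,presentation,17,57,6,18
hyperreflexia,ever,58,116,6,18
speech_changes,presentation,18,77,6,15
speech_changes,ever,59,112,7,15
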