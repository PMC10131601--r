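member_id,month,category,amount_cents,nonimpactable,pregnancy_related,ed_diag_code
T001,3,primary_care,12000,FALSE,FALSE,
T001,4,ED,90000,FALSE,FALSE,R07.9
T001,5,laboratory,8000,TRUE,FALSE,
T002,3,specialist,22000,FALSE,FALSE,
T002,6,inpatient,600000,TRUE,FALSE,
T002,7,mental_health,18000,FALSE,FALSE,
T003,4,ambulatory,40000,FALSE,TRUE,
T003,5,radiology,35000,FALSE,FALSE,
T003,8,total_rx,12000,FALSE,FALSE,
T004,9,home_health,80000,TRUE,TRUE,
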