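code,specialty,cost_per_case,case_share
HBP-PD01,Paediatrics,9000,0.50
HBP-PD02,Paediatrics,12500,0.30
HBP-PD03,Paediatrics,14000,0.20
HBP-GM01,General Medicine,8500,0.40
HBP-GM02,General Medicine,11500,0.40
HBP-GM03,General Medicine,16000,0.20
HBP-OG01,Obstetrics and gynaecology,9500,0.45
HBP-OG02,Obstetrics and gynaecology,15500,0.35
HBP-OG03,Obstetrics and gynaecology,21000,0.20
HBP-EN01,Ear Nose and Throat,11000,0.50
HBP-EN02,Ear Nose and Throat,16500,0.30
HBP-EN03,Ear Nose and Throat,22000,0.20
HBP-GS01,General Surgery,10500,0.40
HBP-GS02,General Surgery,14500,0.40
HBP-GS03,General Surgery,19500,0.20
HBP-OP01,Ophthalmology,8000,0.60
HBP-OP02,Ophthalmology,12000,0.25
HBP-OP03,Ophthalmology,16500,0.15
HBP-OR01,Orthopedics,12000,0.45
HBP-OR02,Orthopedics,16000,0.35
HBP-OR03,Orthopedics,24000,0.20
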