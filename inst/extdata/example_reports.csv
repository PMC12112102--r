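case_id,drug_name,role_code,pt,sex,age,age_unit,country,event_year,outcomes
CASE0000001,BGDRUG_05,PRIMARY_SUSPECT,EVT_0001,,,,US,2021,
CASE0000002,BGDRUG_03,PRIMARY_SUSPECT,EVT_0003,,69,YR,US,2020,
CASE0000002,BGDRUG_03,PRIMARY_SUSPECT,EVT_0019,,69,YR,US,2020,
CASE0000003,DRUG_X,PRIMARY_SUSPECT,EVT_0035,F,,,US,2024,
CASE0000003,DRUG_X,PRIMARY_SUSPECT,EVT_0012,F,,,US,2024,
CASE0000004,DRUG_X,PRIMARY_SUSPECT,EVT_0001,,,,US,2020,
CASE0000004,DRUG_X,PRIMARY_SUSPECT,EVT_0056,,,,US,2020,
CASE0000004,DRUG_X,PRIMARY_SUSPECT,EVT_0028,,,,US,2020,
CASE0000004,DRUG_X,PRIMARY_SUSPECT,EVT_0013,,,,US,2020,
CASE0000005,BGDRUG_03,PRIMARY_SUSPECT,EVT_0006,,,,US,2022,HO
CASE0000005,BGDRUG_03,PRIMARY_SUSPECT,EVT_0008,,,,US,2022,HO
CASE0000006,DRUG_X,PRIMARY_SUSPECT,EVT_0004,,82,YR,US,2020,
CASE0000006,DRUG_X,PRIMARY_SUSPECT,EVT_0036,,82,YR,US,2020,
CASE0000006,DRUG_X,PRIMARY_SUSPECT,EVT_0033,,82,YR,US,2020,
CASE0000006,DRUG_X,PRIMARY_SUSPECT,EVT_0055,,82,YR,US,2020,
CASE0000007,BGDRUG_05,PRIMARY_SUSPECT,EVT_0020,,,,US,2024,HO
CASE0000007,BGDRUG_05,PRIMARY_SUSPECT,EVT_0008,,,,US,2024,HO
CASE0000007,BGDRUG_05,PRIMARY_SUSPECT,EVT_0005,,,,US,2024,HO
CASE0000008,BGDRUG_04,PRIMARY_SUSPECT,EVT_0017,,,,US,2024,
CASE0000009,DRUG_X,PRIMARY_SUSPECT,EVT_0006,,,,US,2020,HO
CASE0000009,DRUG_X,PRIMARY_SUSPECT,EVT_0010,,,,US,2020,HO
CASE0000009,DRUG_X,PRIMARY_SUSPECT,EVT_0008,,,,US,2020,HO
CASE0000009,DRUG_X,PRIMARY_SUSPECT,EVT_0019,,,,US,2020,HO
CASE0000009,DRUG_X,PRIMARY_SUSPECT,EVT_0001,,,,US,2020,HO
CASE0000010,BGDRUG_02,PRIMARY_SUSPECT,EVT_0003,,,,US,2022,
CASE0000010,BGDRUG_02,PRIMARY_SUSPECT,EVT_0037,,,,US,2022,
CASE0000010,BGDRUG_02,PRIMARY_SUSPECT,EVT_0038,,,,US,2022,
CASE0000011,DRUG_X,PRIMARY_SUSPECT,EVT_0002,M,,,US,2021,
CASE0000011,DRUG_X,PRIMARY_SUSPECT,EVT_0042,M,,,US,2021,
CASE0000012,BGDRUG_04,PRIMARY_SUSPECT,EVT_0003,,,,US,2023,HO
CASE0000012,BGDRUG_04,PRIMARY_SUSPECT,EVT_0016,,,,US,2023,HO
CASE0000012,BGDRUG_04,PRIMARY_SUSPECT,EVT_0021,,,,US,2023,HO
CASE0000012,BGDRUG_04,PRIMARY_SUSPECT,EVT_0001,,,,US,2023,HO
CASE0000013,DRUG_X,PRIMARY_SUSPECT,EVT_0003,,60,YR,US,2023,DE
CASE0000013,DRUG_X,PRIMARY_SUSPECT,EVT_0001,,60,YR,US,2023,DE
CASE0000014,BGDRUG_05,PRIMARY_SUSPECT,EVT_0005,,,,US,2023,DE
CASE0000014,BGDRUG_05,PRIMARY_SUSPECT,EVT_0013,,,,US,2023,DE
CASE0000014,BGDRUG_05,PRIMARY_SUSPECT,EVT_0045,,,,US,2023,DE
CASE0000015,DRUG_X,PRIMARY_SUSPECT,EVT_0009,,,,US,2021,
CASE0000015,DRUG_X,PRIMARY_SUSPECT,EVT_0002,,,,US,2021,
CASE0000015,DRUG_X,PRIMARY_SUSPECT,EVT_0007,,,,US,2021,
CASE0000015,DRUG_X,PRIMARY_SUSPECT,EVT_0005,,,,US,2021,
CASE0000016,BGDRUG_04,PRIMARY_SUSPECT,EVT_0005,,,,US,2023,
CASE0000016,BGDRUG_04,PRIMARY_SUSPECT,EVT_0044,,,,US,2023,
CASE0000016,BGDRUG_04,PRIMARY_SUSPECT,EVT_0002,,,,US,2023,
CASE0000016,BGDRUG_04,PRIMARY_SUSPECT,EVT_0004,,,,US,2023,
CASE0000017,BGDRUG_05,PRIMARY_SUSPECT,EVT_0023,,,,US,2022,
CASE0000017,BGDRUG_05,PRIMARY_SUSPECT,EVT_0002,,,,US,2022,
CASE0000017,BGDRUG_05,PRIMARY_SUSPECT,EVT_0010,,,,US,2022,
CASE0000017,BGDRUG_05,PRIMARY_SUSPECT,EVT_0011,,,,US,2022,
CASE0000018,DRUG_X,PRIMARY_SUSPECT,EVT_0059,,,,US,2023,DE;HO
CASE0000018,DRUG_X,PRIMARY_SUSPECT,EVT_0017,,,,US,2023,DE;HO
CASE0000018,DRUG_X,PRIMARY_SUSPECT,EVT_0022,,,,US,2023,DE;HO
CASE0000018,DRUG_X,PRIMARY_SUSPECT,EVT_0002,,,,US,2023,DE;HO
CASE0000018,DRUG_X,PRIMARY_SUSPECT,EVT_0020,,,,US,2023,DE;HO
CASE0000019,BGDRUG_05,PRIMARY_SUSPECT,EVT_0004,,,,US,2024,
CASE0000019,BGDRUG_05,PRIMARY_SUSPECT,EVT_0002,,,,US,2024,
CASE0000019,BGDRUG_05,PRIMARY_SUSPECT,EVT_0007,,,,US,2024,
CASE0000020,DRUG_X,PRIMARY_SUSPECT,EVT_0004,,,,US,2021,
CASE0000020,DRUG_X,PRIMARY_SUSPECT,EVT_0001,,,,US,2021,
CASE0000020,DRUG_X,PRIMARY_SUSPECT,EVT_0003,,,,US,2021,
CASE0000020,DRUG_X,PRIMARY_SUSPECT,EVT_0013,,,,US,2021,
CASE0000020,DRUG_X,PRIMARY_SUSPECT,EVT_0002,,,,US,2021,
CASE0000021,BGDRUG_01,PRIMARY_SUSPECT,EVT_0048,F,,,US,2023,LT;HO
CASE0000021,BGDRUG_01,PRIMARY_SUSPECT,EVT_0001,F,,,US,2023,LT;HO
CASE0000021,BGDRUG_01,PRIMARY_SUSPECT,EVT_0029,F,,,US,2023,LT;HO
CASE0000021,BGDRUG_01,PRIMARY_SUSPECT,EVT_0006,F,,,US,2023,LT;HO
CASE0000022,BGDRUG_03,PRIMARY_SUSPECT,EVT_0002,,,,US,2024,HO
CASE0000023,DRUG_X,PRIMARY_SUSPECT,EVT_0001,,,,JP,2024,OT
CASE0000023,DRUG_X,PRIMARY_SUSPECT,EVT_0016,,,,JP,2024,OT
CASE0000023,DRUG_X,PRIMARY_SUSPECT,EVT_0026,,,,JP,2024,OT
CASE0000023,DRUG_X,PRIMARY_SUSPECT,EVT_0006,,,,JP,2024,OT
CASE0000024,DRUG_X,PRIMARY_SUSPECT,EVT_0027,,,,US,2024,
CASE0000024,DRUG_X,PRIMARY_SUSPECT,EVT_0004,,,,US,2024,
CASE0000024,DRUG_X,PRIMARY_SUSPECT,EVT_0002,,,,US,2024,
CASE0000025,BGDRUG_05,PRIMARY_SUSPECT,EVT_0024,,,,US,2022,HO
CASE0000025,BGDRUG_05,PRIMARY_SUSPECT,EVT_0002,,,,US,2022,HO
CASE0000025,BGDRUG_05,PRIMARY_SUSPECT,EVT_0019,,,,US,2022,HO
CASE0000025,BGDRUG_05,PRIMARY_SUSPECT,EVT_0001,,,,US,2022,HO
CASE0000026,DRUG_X,PRIMARY_SUSPECT,EVT_0026,,,,US,2022,OT
CASE0000026,DRUG_X,PRIMARY_SUSPECT,EVT_0001,,,,US,2022,OT
CASE0000027,BGDRUG_03,PRIMARY_SUSPECT,EVT_0013,,,,US,2024,HO
CASE0000027,BGDRUG_03,PRIMARY_SUSPECT,EVT_0001,,,,US,2024,HO
CASE0000028,DRUG_X,PRIMARY_SUSPECT,EVT_0001,,,,US,2022,
CASE0000028,DRUG_X,PRIMARY_SUSPECT,EVT_0006,,,,US,2022,
CASE0000028,DRUG_X,PRIMARY_SUSPECT,EVT_0004,,,,US,2022,
CASE0000029,DRUG_X,CONCOMITANT,EVT_0038,,,,US,2023,
CASE0000029,DRUG_X,CONCOMITANT,EVT_0001,,,,US,2023,
CASE0000029,DRUG_X,CONCOMITANT,EVT_0005,,,,US,2023,
CASE0000029,DRUG_X,CONCOMITANT,EVT_0023,,,,US,2023,
CASE0000030,BGDRUG_01,PRIMARY_SUSPECT,EVT_0025,,,,US,2021,HO
CASE0000030,BGDRUG_01,PRIMARY_SUSPECT,EVT_0040,,,,US,2021,HO
CASE0000030,BGDRUG_01,PRIMARY_SUSPECT,EVT_0003,,,,US,2021,HO
CASE0000005,BGDRUG_03,PRIMARY_SUSPECT,EVT_0006,,,,US,2021,HO
CASE0000005,BGDRUG_03,PRIMARY_SUSPECT,EVT_0008,,,,US,2021,HO
CASE0000016,BGDRUG_04,PRIMARY_SUSPECT,EVT_0005,,,,US,2022,
CASE0000016,BGDRUG_04,PRIMARY_SUSPECT,EVT_0044,,,,US,2022,
CASE0000016,BGDRUG_04,PRIMARY_SUSPECT,EVT_0002,,,,US,2022,
CASE0000016,BGDRUG_04,PRIMARY_SUSPECT,EVT_0004,,,,US,2022,
CASE0000017,BGDRUG_05,PRIMARY_SUSPECT,EVT_0023,,,,US,2021,
CASE0000017,BGDRUG_05,PRIMARY_SUSPECT,EVT_0002,,,,US,2021,
CASE0000017,BGDRUG_05,PRIMARY_SUSPECT,EVT_0010,,,,US,2021,
CASE0000017,BGDRUG_05,PRIMARY_SUSPECT,EVT_0011,,,,US,2021,
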