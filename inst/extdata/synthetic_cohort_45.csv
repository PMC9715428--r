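patient_id,pb_cd34,ap_cd34,age_years,age_group,sex,mobilization,tumor_type,arm
P001,62.0938482453866,7.91560455701632,6.13880315539973,6-<12,female,G-CSF,neuroblastoma,G-CSF alone
P002,58.6363195429996,10.219680358298,2.36904408558595,1-<6,male,G-CSF,ewing_sarcoma,G-CSF alone
P003,54.2365068752719,10.3210846946692,7.45341193140192,6-<12,female,G-CSF,ewing_sarcoma,plerixafor+G-CSF
P004,46.1090972803407,7.73980579658198,5.43297075807993,1-<6,female,G-CSF,ewing_sarcoma,G-CSF alone
P005,42.5970545670042,8.88277152014262,7.03755344546022,6-<12,male,G-CSF,neuroblastoma,plerixafor+G-CSF
P006,41.5991192062645,9.20455397073945,3.98241241146461,1-<6,female,G-CSF/chemotherapy,neuroblastoma,G-CSF alone
P007,51.9275233736397,17.9021777049735,3.21068073104499,1-<6,male,G-CSF/chemotherapy,neuroblastoma,plerixafor+G-CSF
P008,47.0461838297307,4.40878807727746,2.55808523606431,1-<6,male,G-CSF,neuroblastoma,plerixafor+G-CSF
P009,60.1285745615062,6.61037820737317,7.60333965251137,6-<12,female,G-CSF,neuroblastoma,G-CSF alone
P010,19.389241323318,4.92077291158124,4.62668396376915,1-<6,male,G-CSF,neuroblastoma,G-CSF alone
P011,12.0491862718875,5.06228998198783,8.14045564510167,6-<12,male,G-CSF,neuroblastoma,plerixafor+G-CSF
P012,19.7860338216125,3.4571711227768,3.21694766804208,1-<6,male,G-CSF,neuroblastoma,plerixafor+G-CSF
P013,53.5385175116618,4.63272177970845,2.95709283745351,1-<6,female,G-CSF,neuroblastoma,plerixafor+G-CSF
P014,71.2848632059248,11.0226009815262,4.47451763786611,1-<6,female,G-CSF,other,plerixafor+G-CSF
P015,47.6233506349933,4.85941500197711,2.44710742519947,1-<6,female,G-CSF,neuroblastoma,G-CSF alone
P016,43.5462420331252,5.6508490773504,9.04224560911759,6-<12,male,G-CSF,ewing_sarcoma,plerixafor+G-CSF
P017,17.7166550156514,1.78590932517125,7.10433877651769,6-<12,male,G-CSF,lymphoma,plerixafor+G-CSF
P018,35.8315098159752,5.97010015196362,2.04092764429852,1-<6,female,G-CSF/chemotherapy,neuroblastoma,plerixafor+G-CSF
P019,23.0476637894554,1.46669662715221,12.2512845828967,>=12,female,G-CSF,ewing_sarcoma,G-CSF alone
P020,26.9680313358053,4.01411416047898,14.4838452149272,>=12,male,G-CSF,ewing_sarcoma,G-CSF alone
P021,24.962752868337,2.87839763412773,11.8654549282584,6-<12,male,G-CSF,ewing_sarcoma,plerixafor+G-CSF
P022,30.2656761423959,10.3493620389438,6.54516715608975,6-<12,male,G-CSF/chemotherapy,neuroblastoma,plerixafor+G-CSF
P023,51.0641057699835,9.55247667890799,5.04145901403282,1-<6,male,G-CSF,neuroblastoma,plerixafor+G-CSF
P024,47.2118831782676,6.02667605600469,2.6278161586066,1-<6,male,G-CSF,neuroblastoma,plerixafor+G-CSF
P025,30.8593676777157,2.75777530344007,9.21449067157283,6-<12,male,G-CSF,ewing_sarcoma,G-CSF alone
P026,107.868600025426,5.34590160741723,14.3353034787657,>=12,female,G-CSF/chemotherapy,ewing_sarcoma,G-CSF alone
P027,47.6317793254278,9.62379677981799,13.0860928118907,>=12,male,G-CSF,ewing_sarcoma,plerixafor+G-CSF
P028,89.105773588602,6.93740201201003,12.7824320036855,>=12,male,G-CSF,ewing_sarcoma,plerixafor+G-CSF
P029,35.2925863101039,7.80956670452855,9.54306882260678,6-<12,female,G-CSF,lymphoma,plerixafor+G-CSF
P030,15.171327212053,3.03944220796173,5.0356537013129,1-<6,male,G-CSF/chemotherapy,neuroblastoma,plerixafor+G-CSF
P031,27.0637040023871,4.59433772076448,7.07306346725783,6-<12,male,G-CSF,lymphoma,plerixafor+G-CSF
P032,19.5196927843099,0.563881417484045,17.6994858385656,>=12,female,G-CSF,ewing_sarcoma,plerixafor+G-CSF
P033,15.8124316477371,2.00882356165232,8.6849482630319,6-<12,male,G-CSF,ewing_sarcoma,G-CSF alone
P034,18.2304816709552,1.99764122206913,7.17442265496011,6-<12,male,G-CSF,other,plerixafor+G-CSF
P035,13.8608570996109,5.15760044766812,6.9300527125801,6-<12,female,G-CSF,neuroblastoma,G-CSF alone
P036,34.0996158809938,5.93841554432726,16.3062629475508,>=12,male,G-CSF,other,plerixafor+G-CSF
P037,26.1409635375615,4.57627123731141,8.05188927726914,6-<12,male,G-CSF,lymphoma,plerixafor+G-CSF
P038,22.8481388869469,2.4939483508034,12.581571082455,>=12,male,G-CSF,lymphoma,plerixafor+G-CSF
P039,17.7488197549917,4.55636456025347,2.6347570406739,1-<6,male,G-CSF,ewing_sarcoma,G-CSF alone
P040,74.4245250288785,17.4186927677792,11.0678717808497,6-<12,male,G-CSF,ewing_sarcoma,plerixafor+G-CSF
P041,22.4063360483663,6.30087432043856,3.33456021390914,1-<6,male,G-CSF,neuroblastoma,plerixafor+G-CSF
P042,63.9991126673839,13.5771547693126,5.81275746494807,1-<6,male,G-CSF,neuroblastoma,plerixafor+G-CSF
P043,57.7787621301067,5.62585087834662,2.50344762653935,1-<6,female,G-CSF,neuroblastoma,G-CSF alone
P044,21.4718022311044,2.67190600054473,1.12111543425586,1-<6,female,G-CSF,lymphoma,plerixafor+G-CSF
P045,7.01451992148047,0.10773911476922,2.02462317511901,1-<6,male,G-CSF,other,G-CSF alone
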