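review_id,research_area,d1,d2,d3,d4,overall
Kelly_2014,physical_activity,low,high,high,high,
Samitz_2011,physical_activity,low,low,high,high,
Woodcock_2011,physical_activity,high,high,unclear,low,
Hupin_2015,physical_activity,low,high,unclear,low,
Biswas_2015,sedentary_behavior,low,high,low,high,
Chau_2013,sedentary_behavior,high,high,low,high,
Grontved_2011,sedentary_behavior,low,high,high,high,
Wilmot_2012,sedentary_behavior,high,high,low,high,
Ford_2012,sedentary_behavior,high,high,high,high,
Pandey_2016,sedentary_behavior,high,high,unclear,unclear,
Sun_2015,sedentary_behavior,high,unclear,high,high,
Costanzo_2011,alcohol,high,high,unclear,high,
Jayasekara_2014,alcohol,low,high,high,high,
Roerecke_2011,alcohol,low,high,high,low,
Roerecke_2014a,alcohol,low,high,high,high,
Ronksley_2011,alcohol,low,low,high,low,
Park_2015,alcohol,high,high,high,high,
Stockwell_2016,alcohol,low,high,unclear,low,
Zheng_2015,alcohol,high,low,low,low,
Roerecke_2010,alcohol,high,high,high,high,
Roerecke_2014b,alcohol,low,high,high,high,
Gellert_2012,smoking,low,unclear,unclear,unclear,
Lv_2015,smoking,low,high,unclear,high,
Sinha_2016,smoking,low,high,high,high,
Farvid_2014,diet,low,high,high,high,
Graudal_2014,diet,low,high,high,high,
Hu_2014,diet,low,high,high,high,
Li_2012,diet,high,high,high,high,
MusaVeloso_2011,diet,high,high,high,high,
Pan_2012,diet,high,high,low,high,
Poggio_2015,diet,low,high,high,low,
Schwingshackl_2014,diet,low,low,high,high,
Wang_2014,diet,low,high,low,high,
Chen_2016,diet,low,low,low,low,
Cheng_2015,diet,low,high,low,high,
Cheng_2016,diet,low,high,low,high,
DeSouza_2015,diet,low,high,high,low,
Narain_2016,diet,low,low,high,low,
Bukkapatnam_2010,statin,high,high,high,high,
Kizer_2010,statin,low,high,high,high,
Kostis_2012,statin,high,high,high,low,
Lv_2014,statin,high,high,high,low,
Ray_2010,statin,high,high,high,high,
Savarese_2013,statin,low,high,low,low,
Taylor_2011,statin,low,low,low,low,
Tonelli_2011,statin,low,high,low,high,
Chou_2016,statin,low,high,low,low,
Preiss_2015,statin,low,high,high,low,
Teng_2015,statin,low,high,low,low,
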