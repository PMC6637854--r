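domain,category,rung
food environment,nutrition labelling on packaged food,provide information
food environment,menu and shelf labelling in retail and food service,provide information
food environment,subsidies to reduce the price of fruits and vegetables,guide choice with incentives
food environment,targeted food vouchers for low-income households,guide choice with incentives
food environment,taxes on unhealthy foods and beverages,guide choice with disincentives
food environment,incentives for store-owners to locate in underserved areas,enable choice
food environment,standards for food offered in public institutions,guide choice by changing default
food environment,restrictions on food marketing to children,restrict choice
food environment,bans on specified ingredients in food service,eliminate choice
food system/supply,supply-chain incentives for horticultural production,enable choice
food system/supply,public procurement standards favouring fresh produce,guide choice by changing default
food system/supply,school fruit and vegetable provision schemes,enable choice
behaviour change communication,food-based dietary guidelines,provide information
behaviour change communication,public awareness and mass-media campaigns,provide information
behaviour change communication,nutrition advice in primary care,provide information
behaviour change communication,nutrition education and skills in schools,provide information
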