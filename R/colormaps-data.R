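# 256-entry lookup tables for the Turbo, Viridis and Inferno colormaps
# (standard published sRGB tables, stored as hex so the package needs no
# plotting library at render time).

.turbo_lut <- c(
  "#30123B", "#321543", "#33184A", "#341B51", "#351E58", "#36215F", "#372466", "#38276D",
  "#392A73", "#3A2D79", "#3B2F80", "#3C3286", "#3D358B", "#3E3891", "#3F3B97", "#3F3E9C",
  "#4040A2", "#4143A7", "#4146AC", "#4249B1", "#424BB5", "#434EBA", "#4451BF", "#4454C3",
  "#4456C7", "#4559CB", "#455CCF", "#455ED3", "#4661D6", "#4664DA", "#4666DD", "#4669E0",
  "#466BE3", "#476EE6", "#4771E9", "#4773EB", "#4776EE", "#4778F0", "#477BF2", "#467DF4",
  "#4680F6", "#4682F8", "#4685FA", "#4687FB", "#458AFC", "#458CFD", "#448FFE", "#4391FE",
  "#4294FF", "#4196FF", "#4099FF", "#3E9BFE", "#3D9EFE", "#3BA0FD", "#3AA3FC", "#38A5FB",
  "#37A8FA", "#35ABF8", "#33ADF7", "#31AFF5", "#2FB2F4", "#2EB4F2", "#2CB7F0", "#2AB9EE",
  "#28BCEB", "#27BEE9", "#25C0E7", "#23C3E4", "#22C5E2", "#20C7DF", "#1FC9DD", "#1ECBDA",
  "#1CCDD8", "#1BD0D5", "#1AD2D2", "#1AD4D0", "#19D5CD", "#18D7CA", "#18D9C8", "#18DBC5",
  "#18DDC2", "#18DEC0", "#18E0BD", "#19E2BB", "#19E3B9", "#1AE4B6", "#1CE6B4", "#1DE7B2",
  "#1FE9AF", "#20EAAC", "#22EBAA", "#25ECA7", "#27EEA4", "#2AEFA1", "#2CF09E", "#2FF19B",
  "#32F298", "#35F394", "#38F491", "#3CF58E", "#3FF68A", "#43F787", "#46F884", "#4AF880",
  "#4EF97D", "#52FA7A", "#55FA76", "#59FB73", "#5DFC6F", "#61FC6C", "#65FD69", "#69FD66",
  "#6DFE62", "#71FE5F", "#75FE5C", "#79FE59", "#7DFF56", "#80FF53", "#84FF51", "#88FF4E",
  "#8BFF4B", "#8FFF49", "#92FF47", "#96FE44", "#99FE42", "#9CFE40", "#9FFD3F", "#A1FD3D",
  "#A4FC3C", "#A7FC3A", "#A9FB39", "#ACFB38", "#AFFA37", "#B1F936", "#B4F836", "#B7F735",
  "#B9F635", "#BCF534", "#BEF434", "#C1F334", "#C3F134", "#C6F034", "#C8EF34", "#CBED34",
  "#CDEC34", "#D0EA34", "#D2E935", "#D4E735", "#D7E535", "#D9E436", "#DBE236", "#DDE037",
  "#DFDF37", "#E1DD37", "#E3DB38", "#E5D938", "#E7D739", "#E9D539", "#EBD339", "#ECD13A",
  "#EECF3A", "#EFCD3A", "#F1CB3A", "#F2C93A", "#F4C73A", "#F5C53A", "#F6C33A", "#F7C13A",
  "#F8BE39", "#F9BC39", "#FABA39", "#FBB838", "#FBB637", "#FCB336", "#FCB136", "#FDAE35",
  "#FDAC34", "#FEA933", "#FEA732", "#FEA431", "#FEA130", "#FE9E2F", "#FE9B2D", "#FE992C",
  "#FE962B", "#FE932A", "#FE9029", "#FD8D27", "#FD8A26", "#FC8725", "#FC8423", "#FB8122",
  "#FB7E21", "#FA7B1F", "#F9781E", "#F9751D", "#F8721C", "#F76F1A", "#F66C19", "#F56918",
  "#F46617", "#F36315", "#F26014", "#F15D13", "#F05B12", "#EF5811", "#ED5510", "#EC530F",
  "#EB500E", "#EA4E0D", "#E84B0C", "#E7490C", "#E5470B", "#E4450A", "#E2430A", "#E14109",
  "#DF3F08", "#DD3D08", "#DC3B07", "#DA3907", "#D83706", "#D63506", "#D43305", "#D23105",
  "#D02F05", "#CE2D04", "#CC2B04", "#CA2A04", "#C82803", "#C52603", "#C32503", "#C12302",
  "#BE2102", "#BC2002", "#B91E02", "#B71D02", "#B41B01", "#B21A01", "#AF1801", "#AC1701",
  "#A91601", "#A71401", "#A41301", "#A11201", "#9E1001", "#9B0F01", "#980E01", "#950D01",
  "#920B01", "#8E0A01", "#8B0902", "#880802", "#850702", "#810602", "#7E0502", "#7A0403"
)

.viridis_lut <- c(
  "#440154", "#440256", "#450457", "#450559", "#46075A", "#46085C", "#460A5D", "#460B5E",
  "#470D60", "#470E61", "#471063", "#471164", "#471365", "#481467", "#481668", "#481769",
  "#48186A", "#481A6C", "#481B6D", "#481C6E", "#481D6F", "#481F70", "#482071", "#482173",
  "#482374", "#482475", "#482576", "#482677", "#482878", "#482979", "#472A7A", "#472C7A",
  "#472D7B", "#472E7C", "#472F7D", "#46307E", "#46327E", "#46337F", "#463480", "#453581",
  "#453781", "#453882", "#443983", "#443A83", "#443B84", "#433D84", "#433E85", "#423F85",
  "#424086", "#424186", "#414287", "#414487", "#404588", "#404688", "#3F4788", "#3F4889",
  "#3E4989", "#3E4A89", "#3E4C8A", "#3D4D8A", "#3D4E8A", "#3C4F8A", "#3C508B", "#3B518B",
  "#3B528B", "#3A538B", "#3A548C", "#39558C", "#39568C", "#38588C", "#38598C", "#375A8C",
  "#375B8D", "#365C8D", "#365D8D", "#355E8D", "#355F8D", "#34608D", "#34618D", "#33628D",
  "#33638D", "#32648E", "#32658E", "#31668E", "#31678E", "#31688E", "#30698E", "#306A8E",
  "#2F6B8E", "#2F6C8E", "#2E6D8E", "#2E6E8E", "#2E6F8E", "#2D708E", "#2D718E", "#2C718E",
  "#2C728E", "#2C738E", "#2B748E", "#2B758E", "#2A768E", "#2A778E", "#2A788E", "#29798E",
  "#297A8E", "#297B8E", "#287C8E", "#287D8E", "#277E8E", "#277F8E", "#27808E", "#26818E",
  "#26828E", "#26828E", "#25838E", "#25848E", "#25858E", "#24868E", "#24878E", "#23888E",
  "#23898E", "#238A8D", "#228B8D", "#228C8D", "#228D8D", "#218E8D", "#218F8D", "#21908D",
  "#21918C", "#20928C", "#20928C", "#20938C", "#1F948C", "#1F958B", "#1F968B", "#1F978B",
  "#1F988B", "#1F998A", "#1F9A8A", "#1E9B8A", "#1E9C89", "#1E9D89", "#1F9E89", "#1F9F88",
  "#1FA088", "#1FA188", "#1FA187", "#1FA287", "#20A386", "#20A486", "#21A585", "#21A685",
  "#22A785", "#22A884", "#23A983", "#24AA83", "#25AB82", "#25AC82", "#26AD81", "#27AD81",
  "#28AE80", "#29AF7F", "#2AB07F", "#2CB17E", "#2DB27D", "#2EB37C", "#2FB47C", "#31B57B",
  "#32B67A", "#34B679", "#35B779", "#37B878", "#38B977", "#3ABA76", "#3BBB75", "#3DBC74",
  "#3FBC73", "#40BD72", "#42BE71", "#44BF70", "#46C06F", "#48C16E", "#4AC16D", "#4CC26C",
  "#4EC36B", "#50C46A", "#52C569", "#54C568", "#56C667", "#58C765", "#5AC864", "#5CC863",
  "#5EC962", "#60CA60", "#63CB5F", "#65CB5E", "#67CC5C", "#69CD5B", "#6CCD5A", "#6ECE58",
  "#70CF57", "#73D056", "#75D054", "#77D153", "#7AD151", "#7CD250", "#7FD34E", "#81D34D",
  "#84D44B", "#86D549", "#89D548", "#8BD646", "#8ED645", "#90D743", "#93D741", "#95D840",
  "#98D83E", "#9BD93C", "#9DD93B", "#A0DA39", "#A2DA37", "#A5DB36", "#A8DB34", "#AADC32",
  "#ADDC30", "#B0DD2F", "#B2DD2D", "#B5DE2B", "#B8DE29", "#BADE28", "#BDDF26", "#C0DF25",
  "#C2DF23", "#C5E021", "#C8E020", "#CAE11F", "#CDE11D", "#D0E11C", "#D2E21B", "#D5E21A",
  "#D8E219", "#DAE319", "#DDE318", "#DFE318", "#E2E418", "#E5E419", "#E7E419", "#EAE51A",
  "#ECE51B", "#EFE51C", "#F1E51D", "#F4E61E", "#F6E620", "#F8E621", "#FBE723", "#FDE725"
)

.inferno_lut <- c(
  "#000004", "#010005", "#010106", "#010108", "#02010A", "#02020C", "#02020E", "#030210",
  "#040312", "#040314", "#050417", "#060419", "#07051B", "#08051D", "#09061F", "#0A0722",
  "#0B0724", "#0C0826", "#0D0829", "#0E092B", "#10092D", "#110A30", "#120A32", "#140B34",
  "#150B37", "#160B39", "#180C3C", "#190C3E", "#1B0C41", "#1C0C43", "#1E0C45", "#1F0C48",
  "#210C4A", "#230C4C", "#240C4F", "#260C51", "#280B53", "#290B55", "#2B0B57", "#2D0B59",
  "#2F0A5B", "#310A5C", "#320A5E", "#340A5F", "#360961", "#380962", "#390963", "#3B0964",
  "#3D0965", "#3E0966", "#400A67", "#420A68", "#440A68", "#450A69", "#470B6A", "#490B6A",
  "#4A0C6B", "#4C0C6B", "#4D0D6C", "#4F0D6C", "#510E6C", "#520E6D", "#540F6D", "#550F6D",
  "#57106E", "#59106E", "#5A116E", "#5C126E", "#5D126E", "#5F136E", "#61136E", "#62146E",
  "#64156E", "#65156E", "#67166E", "#69166E", "#6A176E", "#6C186E", "#6D186E", "#6F196E",
  "#71196E", "#721A6E", "#741A6E", "#751B6E", "#771C6D", "#781C6D", "#7A1D6D", "#7C1D6D",
  "#7D1E6D", "#7F1E6C", "#801F6C", "#82206C", "#84206B", "#85216B", "#87216B", "#88226A",
  "#8A226A", "#8C2369", "#8D2369", "#8F2469", "#902568", "#922568", "#932667", "#952667",
  "#972766", "#982766", "#9A2865", "#9B2964", "#9D2964", "#9F2A63", "#A02A63", "#A22B62",
  "#A32C61", "#A52C60", "#A62D60", "#A82E5F", "#A92E5E", "#AB2F5E", "#AD305D", "#AE305C",
  "#B0315B", "#B1325A", "#B3325A", "#B43359", "#B63458", "#B73557", "#B93556", "#BA3655",
  "#BC3754", "#BD3853", "#BF3952", "#C03A51", "#C13A50", "#C33B4F", "#C43C4E", "#C63D4D",
  "#C73E4C", "#C83F4B", "#CA404A", "#CB4149", "#CC4248", "#CE4347", "#CF4446", "#D04545",
  "#D24644", "#D34743", "#D44842", "#D54A41", "#D74B3F", "#D84C3E", "#D94D3D", "#DA4E3C",
  "#DB503B", "#DD513A", "#DE5238", "#DF5337", "#E05536", "#E15635", "#E25734", "#E35933",
  "#E45A31", "#E55C30", "#E65D2F", "#E75E2E", "#E8602D", "#E9612B", "#EA632A", "#EB6429",
  "#EB6628", "#EC6726", "#ED6925", "#EE6A24", "#EF6C23", "#EF6E21", "#F06F20", "#F1711F",
  "#F1731D", "#F2741C", "#F3761B", "#F37819", "#F47918", "#F57B17", "#F57D15", "#F67E14",
  "#F68013", "#F78212", "#F78410", "#F8850F", "#F8870E", "#F8890C", "#F98B0B", "#F98C0A",
  "#F98E09", "#FA9008", "#FA9207", "#FA9407", "#FB9606", "#FB9706", "#FB9906", "#FB9B06",
  "#FB9D07", "#FC9F07", "#FCA108", "#FCA309", "#FCA50A", "#FCA60C", "#FCA80D", "#FCAA0F",
  "#FCAC11", "#FCAE12", "#FCB014", "#FCB216", "#FCB418", "#FBB61A", "#FBB81D", "#FBBA1F",
  "#FBBC21", "#FBBE23", "#FAC026", "#FAC228", "#FAC42A", "#FAC62D", "#F9C72F", "#F9C932",
  "#F9CB35", "#F8CD37", "#F8CF3A", "#F7D13D", "#F7D340", "#F6D543", "#F6D746", "#F5D949",
  "#F5DB4C", "#F4DD4F", "#F4DF53", "#F4E156", "#F3E35A", "#F3E55D", "#F2E661", "#F2E865",
  "#F2EA69", "#F1EC6D", "#F1ED71", "#F1EF75", "#F1F179", "#F2F27D", "#F2F482", "#F3F586",
  "#F3F68A", "#F4F88E", "#F5F992", "#F6FA96", "#F8FB9A", "#F9FC9D", "#FAFDA1", "#FCFFA4"
)

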