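# Bundled static name lists for the synthetic identity generator, so tests
# and simulations never need network access. Deliberately includes
# diacritics, apostrophes and very short names to exercise normalization,
# match-key slicing and the degenerate-name rules of the corruption model.

cl_first_names <- c(
  "James", "Mary", "Robert", "Patricia", "John", "Jennifer", "Michael",
  "Linda", "David", "Elizabeth", "William", "Barbara", "Richard", "Susan",
  "Joseph", "Jessica", "Thomas", "Sarah", "Charles", "Karen", "Christopher",
  "Nancy", "Daniel", "Lisa", "Matthew", "Margaret", "Anthony", "Betty",
  "Mark", "Sandra", "Donald", "Ashley", "Steven", "Kimberly", "Paul",
  "Emily", "Andrew", "Donna", "Joshua", "Michelle", "Kenneth", "Dorothy",
  "Kevin", "Carol", "Brian", "Amanda", "George", "Melissa", "Edward",
  "Deborah", "Ronald", "Stephanie", "Timothy", "Rebecca", "Jason", "Sharon",
  "Jeffrey", "Laura", "Ryan", "Cynthia", "Jacob", "Kathleen", "Gary", "Amy",
  "Nicholas", "Angela", "Eric", "Shirley", "Jonathan", "Anna", "Stephen",
  "Brenda", "Larry", "Pamela", "Justin", "Emma", "Scott", "Nicole",
  "Brandon", "Helen", "Benjamin", "Samantha", "Samuel", "Katherine",
  "Gregory", "Christine", "Frank", "Debra", "Alexander", "Rachel",
  "Raymond", "Catherine", "Patrick", "Carolyn", "Jack", "Janet", "Dennis",
  "Ruth", "Jerry", "Maria", "Tyler", "Heather", "Aaron", "Diane", "Jose",
  "Virginia", "Adam", "Julie", "Henry", "Joyce", "Nathan", "Victoria",
  "Douglas", "Olivia", "Zachary", "Kelly", "Peter", "Christina", "Kyle",
  "Lauren", "Walter", "Joan", "Ethan", "Evelyn", "Jeremy", "Judith",
  "Harold", "Megan", "Keith", "Cheryl", "Christian", "Andrea", "Roger",
  "Hannah", "Noah", "Martha", "Gerald", "Jacqueline", "Carl", "Frances",
  "Terry", "Gloria", "Sean", "Ann", "Austin", "Teresa", "Arthur", "Kathryn",
  "Lawrence", "Sara", "Jesse", "Janice", "Dylan", "Jean", "Bryan", "Alice",
  "Joe", "Madison", "Jordan", "Doris", "Billy", "Abigail", "Bruce", "Julia",
  "Albert", "Judy", "Willie", "Grace", "Gabriel", "Denise", "Logan",
  "Amber", "Alan", "Marilyn", "Juan", "Danielle", "Wayne", "Beverly",
  "Roy", "Isabella", "Ralph", "Theresa", "Randy", "Diana", "Eugene",
  "Natalie", "Vincent", "Brittany", "Russell", "Charlotte", "Elijah",
  "Marie", "Louis", "Kayla", "Bobby", "Alexis", "Philip", "Lori",
  "Johnny", "José", "René", "Andrés", "María", "Sofía", "Luis", "Ana",
  "Al", "Bo", "Li", "Ed", "Ty"
)

cl_last_names <- c(
  "Smith", "Johnson", "Williams", "Brown", "Jones", "Garcia", "Miller",
  "Davis", "Rodriguez", "Martinez", "Hernandez", "Lopez", "Gonzalez",
  "Wilson", "Anderson", "Thomas", "Taylor", "Moore", "Jackson", "Martin",
  "Lee", "Perez", "Thompson", "White", "Harris", "Sanchez", "Clark",
  "Ramirez", "Lewis", "Robinson", "Walker", "Young", "Allen", "King",
  "Wright", "Scott", "Torres", "Nguyen", "Hill", "Flores", "Green",
  "Adams", "Nelson", "Baker", "Hall", "Rivera", "Campbell", "Mitchell",
  "Carter", "Roberts", "Gomez", "Phillips", "Evans", "Turner", "Diaz",
  "Parker", "Cruz", "Edwards", "Collins", "Reyes", "Stewart", "Morris",
  "Morales", "Murphy", "Cook", "Rogers", "Gutierrez", "Ortiz", "Morgan",
  "Cooper", "Peterson", "Bailey", "Reed", "Kelly", "Howard", "Ramos",
  "Kim", "Cox", "Ward", "Richardson", "Watson", "Brooks", "Chavez",
  "Wood", "James", "Bennett", "Gray", "Mendoza", "Ruiz", "Hughes",
  "Price", "Alvarez", "Castillo", "Sanders", "Patel", "Myers", "Long",
  "Ross", "Foster", "Jimenez", "Powell", "Jenkins", "Perry", "Russell",
  "Sullivan", "Bell", "Coleman", "Butler", "Henderson", "Barnes",
  "Gonzales", "Fisher", "Vasquez", "Simmons", "Romero", "Jordan",
  "Patterson", "Alexander", "Hamilton", "Graham", "Reynolds", "Griffin",
  "Wallace", "Moreno", "West", "Cole", "Hayes", "Bryant", "Herrera",
  "Gibson", "Ellis", "Tran", "Medina", "Aguilar", "Stevens", "Murray",
  "Ford", "Castro", "Marshall", "Owens", "Harrison", "Fernandez",
  "McDonald", "Woods", "Washington", "Kennedy", "Wells", "Vargas",
  "Henry", "Chen", "Freeman", "Webb", "Tucker", "Guzman", "Burns",
  "Crawford", "Olson", "Simpson", "Porter", "Hunter", "Gordon", "Mendez",
  "Silva", "Shaw", "Snyder", "Mason", "Dixon", "Muñoz", "Hunt", "Hicks",
  "Holmes", "Palmer", "Wagner", "Black", "Robertson", "Boyd", "Rose",
  "Stone", "Salazar", "Fox", "Warren", "Mills", "Meyer", "Rice",
  "Schmidt", "Garza", "Daniels", "Ferguson", "Nichols", "Stephens",
  "Soto", "Weaver", "Ryan", "Gardner", "Payne", "Grant", "Dunn",
  "Kelley", "Spencer", "Hawkins", "Arnold", "Pierce", "Vázquez",
  "Hansen", "Peña", "O'Brien", "O'Neil", "García", "Ng", "Wu", "Do"
)
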